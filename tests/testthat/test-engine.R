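test_that("configuration is validated", {
  expect_error(small_config(n_strands = 21L), "even")
  expect_error(small_config(duration = -1), "duration")
  expect_error(small_config(dt = 0), "dt")
  expect_error(small_config(burn_in = -0.1), "burn_in")
  cfg <- small_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(tni_sites(700), seq(3, 700, by = 7))
  expect_length(tni_sites(700), 100)
})

test_that("initialization equilibrates TnI occupancy by calcium level", {
  # absorbing low-calcium limit: detachment off, every TnI stays bound
  cfg <- small_config(n_strands = 10L, burn_in = 0.05)
  r_low <- rates_kb(0)
  st <- init_ensemble(cfg, consistent_chain, r_low)
  expect_true(all(st$tni_bound == 1L))
  expect_true(all(st$site_state == 0L))
  expect_equal(st$time, 0)

  # cold start: burn_in = 0 leaves every TnI bound at t = 0
  st0 <- init_ensemble(small_config(burn_in = 0), consistent_chain,
                       tbl_params$rates)
  expect_true(all(st0$tni_bound == 1L))

  # telegraph oracle: an isolated regulatory site equilibrates to
  # k_I_eff / (k_I_eff + k_-I), with k_I_eff = k_I^o r_I/r_I^o evaluated at
  # the free-chain state of its site (chain solver supplies phi, sigma)
  cfg1 <- small_config(n_strands = 300L, n_sites = 10L, burn_in = 0.3,
                       seed = 21L)
  r <- rates_kb(3)                       # k_-I = 300 /s
  st1 <- init_ensemble(cfg1, consistent_chain, r)
  free_sol <- chain_solution(pinning_profile(10L), consistent_chain)
  site <- tni_sites(10L)
  r_i <- weight_tni_rebind(free_sol$phi_bar[site], free_sol$sigma[site],
                           consistent_chain$phi_minus)
  r_i_o <- weight_tni_rebind(0, consistent_chain$sigma_o,
                             consistent_chain$phi_minus)
  k_eff <- effective_tni_on(r_i, r_i_o, r$k_tni_on)
  p_exp <- mean(k_eff / (k_eff + r$k_tni_off))
  p_obs <- mean(st1$tni_bound)
  # conservative SE: one effective draw per strand (the two regulatory
  # sites of a short strand interact weakly through the chain)
  se <- sqrt(p_exp * (1 - p_exp) / cfg1$n_strands)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("frozen dynamics leave the state unchanged", {
  cfg <- small_config(duration = 0.01, burn_in = 0)
  r0 <- rate_constants(0, 0, 0, 0, 0, 0)
  st <- init_ensemble(cfg, consistent_chain, r0)
  st2 <- mc_step(st, cfg, consistent_chain, r0, n_steps = 500L)
  expect_equal(st2$site_state, st$site_state)
  expect_equal(st2$tni_bound, st$tni_bound)
})

test_that("pure weak detachment decays exponentially", {
  cfg <- small_config(duration = 0.05, n_strands = 200L, n_sites = 140L,
                      burn_in = 0, use_chain = FALSE, seed = 13L)
  r <- rate_constants(0, 20, 0, 0, 0, 0)
  st <- init_ensemble(cfg, consistent_chain, r)
  st$site_state[] <- 1L
  st$tni_bound[] <- 0L
  tr <- run_transient(cfg, consistent_chain, r, state = st)
  n_tot <- cfg$n_strands * cfg$n_sites
  final <- tr$frac_weak[nrow(tr)]
  p_exp <- exp(-20 * 0.05)
  se <- sqrt(p_exp * (1 - p_exp) / n_tot)
  expect_lt(abs(final - p_exp), 3 * se)
})

test_that("transients are reproducible and conserve bookkeeping", {
  cfg <- small_config(duration = 0.03, seed = 5L)
  tr1 <- run_transient(cfg, consistent_chain, tbl_params$rates)
  tr2 <- run_transient(cfg, consistent_chain, tbl_params$rates)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))

  # composition identities at every record
  expect_true(all(tr1$frac_not_R + tr1$frac_strong == 1))
  expect_true(all(tr1$frac_weak >= 0 & tr1$frac_strong >= 0))
  # myosin conservation: recorded M_free reflects the bound fraction
  f <- tr1$frac_weak + tr1$frac_strong
  expect_equal(tr1$M_free, pmax(cfg$m_tot - f * cfg$a_tot, 0),
               tolerance = 1e-12)

  # without myosin nothing ever binds
  cfg0 <- small_config(duration = 0.02, m_tot = 0)
  tr0 <- run_transient(cfg0, consistent_chain, tbl_params$rates)
  expect_true(all(tr0$frac_not_R == 1))
})

test_that("state round-trips through snapshots and zero-step runs", {
  cfg <- small_config(duration = 0.02, n_strands = 6L, seed = 3L)
  tr <- run_transient(cfg, consistent_chain, tbl_params$rates,
                      snapshot_times = 0.02)
  st <- attr(tr, "state")
  st_again <- mc_step(st, cfg, consistent_chain, tbl_params$rates,
                      n_steps = 0L)
  expect_equal(unclass(st_again), unclass(st))
  sn <- transient_snapshots(tr)[[1]]
  expect_equal(sn$site_state, st$site_state)
  # per-strand state counts: free + weak + strong = N
  counts <- apply(sn$site_state, 2, function(v) sum(v %in% 0:2))
  expect_true(all(counts == cfg$n_sites))
})

test_that("halving the timestep changes the transient within Monte Carlo error", {
  mk <- function(dt) small_config(duration = 0.04, n_strands = 100L,
                                  n_sites = 140L, dt = dt, burn_in = 0.02,
                                  seed = 17L)
  r <- rates_kb(3)
  tr_a <- run_transient(mk(2e-5), consistent_chain, r)
  tr_b <- run_transient(mk(1e-5), consistent_chain, r)
  ta <- tr_a$frac_strong[nrow(tr_a)]
  tb <- tr_b$frac_strong[which(tr_b$time == max(tr_a$time))]
  n_tot <- 100L * 140L
  se <- sqrt(max(ta * (1 - ta), tb * (1 - tb)) / n_tot)
  # chain coupling correlates sites over about one regulatory unit, so use
  # an effective sample size of n_sites/7 per strand
  expect_lt(abs(ta - tb), 3 * se * sqrt(7))
})

test_that("high calcium with excess myosin saturates the strong state", {
  cfg <- sim_config(duration = 0.3, a_tot = 0.5e-6, m_tot = 5e-6,
                    n_strands = 60L, n_sites = 350L, dt = 2e-5,
                    burn_in = 0.05, record_every = 200L, seed = 19L)
  tr <- run_transient(cfg, consistent_chain, rates_kb(11.89))
  expect_gt(tr$frac_strong[nrow(tr)], 0.9)
})

test_that("engine chain state stays consistent with the exact solver", {
  cfg <- small_config(duration = 0.03, n_strands = 6L, n_sites = 350L,
                      burn_in = 0.02, seed = 11L)
  tr <- run_transient(cfg, consistent_chain, rates_kb(3),
                      snapshot_times = 0.03)
  sn <- transient_snapshots(tr)[[1]]
  ts <- tni_sites(350L)
  for (s in seq_len(cfg$n_strands)) {
    bound <- ts[sn$tni_bound[, s] == 1L]
    strong <- which(sn$site_state[, s] == 2L)
    pins <- sort(c(bound, strong))
    kinds <- ifelse(pins %in% bound, "tni", "myosin")
    ref <- chain_solution(pinning_profile(350L, pins, kinds),
                          consistent_chain)
    expect_lt(max(abs(ref$phi_bar - sn$phi_bar_deg[, s])), 0.01)
    expect_lt(max(abs(ref$sigma - sn$sigma_deg[, s])), 0.05)
  }
})

test_that("transients export as delimited text", {
  cfg <- small_config(duration = 0.01, n_strands = 4L)
  tr <- run_transient(cfg, consistent_chain, tbl_params$rates)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_transient(tr, path)
  back <- read.delim(path)
  expect_equal(names(back), c("time_s", "frac_not_R", "frac_weak",
                              "frac_strong", "frac_TnI_bound",
                              "M_free_molar"))
  expect_equal(back$frac_not_R, tr$frac_not_R)
})
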