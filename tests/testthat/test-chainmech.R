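test_that("pinning profiles are validated", {
  expect_error(pinning_profile(100, c(5, 5), c("tni", "tni")), "increasing")
  expect_error(pinning_profile(100, 101, "tni"), "outside")
  expect_error(pinning_profile(100, 10, "weak"), "kind")
  pr <- pinning_profile(100, c(3, 10), c("tni", "myosin"))
  expect_s3_class(pr, "pinning_profile")
})

test_that("unpinned chain sits at the closed angle with free-chain SD", {
  pr <- pinning_profile(101)
  sol <- chain_solution(pr, consistent_chain)
  expect_equal(sol$phi_bar, rep(0, 101))
  interior <- 20:82
  expect_equal(sol$sigma[interior],
               rep(consistent_chain$sigma_o, length(interior)),
               tolerance = 0.01)
  # free ends are softer than the bulk: SD rises there
  expect_gt(sol$sigma[1], consistent_chain$sigma_o)
})

test_that("single-pin mean profile matches the closed-form decay", {
  # refine = 5 gives xi * h just under 0.05
  pr <- pinning_profile(151, 76, "myosin")
  mean_f <- solve_mean_angle(pr, consistent_chain, refine = 5L)
  xi <- consistent_chain$xi
  s_pin <- (76 - 1) * 5.5
  s_abs <- abs(mean_f$s - s_pin)
  cf <- 10 * single_pin_profile(s_abs, xi)
  sel <- s_abs <= 4 / xi
  expect_lt(max(abs(mean_f$phi[sel] - cf[sel])) / 10, 0.005)
  # ratio at exactly one persistence length from the pin
  right <- mean_f$s >= s_pin
  at_lp <- approx(mean_f$s[right], mean_f$phi[right],
                  xout = s_pin + 1 / xi)$y
  expect_equal(at_lp / 10, exp(-1) * (cos(1) + sin(1)), tolerance = 0.005)
  # constraint satisfaction at the pin
  sol <- chain_solution(pr, consistent_chain)
  expect_equal(sol$phi_bar[76], 10)
  expect_equal(sol$sigma[76], 0)
  expect_equal(max(sol$phi_bar), 10)
})

test_that("two distant blocked pins decay to the closed state midway", {
  # the decay is an oscillatory exponential with envelope sqrt(2) e^(-xi s),
  # so the two superposed kinks fall below 1 % of |phi_-| once the pins are
  # separated by more than ~11.3/xi (2 sqrt(2) e^(-xi d/2) < 0.01)
  xi <- consistent_chain$xi
  gap_sites <- ceiling(12 / (xi * 5.5))
  pr <- pinning_profile(2 * gap_sites + 60,
                        c(30, 30 + gap_sites), c("tni", "tni"))
  sol <- chain_solution(pr, consistent_chain)
  midpoint <- 30 + gap_sites %/% 2
  expect_lt(abs(sol$phi_bar[midpoint]), 0.01 * 25)
  expect_equal(sol$sigma[midpoint], consistent_chain$sigma_o,
               tolerance = 0.01)
})

test_that("free-chain variance converges to the continuum value", {
  pr <- pinning_profile(101)
  err <- vapply(c(2L, 4L, 8L), function(m) {
    sg <- solve_sigma(pr, consistent_chain, refine = m)
    mid <- (length(sg$sigma) + 1) %/% 2
    abs(sg$sigma[mid] - consistent_chain$sigma_o) / consistent_chain$sigma_o
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], err[1] / 2)         # at least first-order in h
  expect_lt(err[2], 0.01)
})

test_that("mirror-image profiles give mirrored means and equal SDs", {
  n <- 120L
  pr <- pinning_profile(n, c(20, 41, 77), c("tni", "myosin", "tni"))
  pr_m <- pinning_profile(n, n + 1L - c(77, 41, 20), c("tni", "myosin", "tni"))
  a <- chain_solution(pr, consistent_chain)
  b <- chain_solution(pr_m, consistent_chain)
  expect_equal(a$phi_bar, rev(b$phi_bar), tolerance = 1e-10)
  expect_equal(a$sigma, rev(b$sigma), tolerance = 1e-10)
})

test_that("conditioning on an extra pin never increases the SD", {
  n <- 150L
  pr <- pinning_profile(n, c(10, 52, 101), c("tni", "tni", "myosin"))
  pr2 <- pinning_profile(n, c(10, 52, 80, 101),
                         c("tni", "tni", "myosin", "myosin"))
  a <- chain_solution(pr, consistent_chain)
  b <- chain_solution(pr2, consistent_chain)
  expect_true(all(b$sigma <= a$sigma + 1e-9))
})

test_that("an isolated two-pin solve matches the global solve when pins are far apart", {
  # with further pins beyond one persistence length the pair picture holds;
  # at dense TnI spacing it does not, and the whole-chain solve is the
  # reference (see the methods vignette)
  xi <- consistent_chain$xi
  far <- ceiling(9 / (xi * 5.5))
  n <- 4L * far
  sites <- c(far, 2L * far, 3L * far)
  pr_all <- pinning_profile(n, sites, c("tni", "myosin", "tni"))
  glob <- chain_solution(pr_all, consistent_chain)
  pr_pair <- pinning_profile(n, sites[1:2], c("tni", "myosin"))
  pair <- chain_solution(pr_pair, consistent_chain)
  seg <- (sites[1] + 1):(sites[2] - 1)
  expect_lt(max(abs(glob$phi_bar[seg] - pair$phi_bar[seg])) / 25, 0.01)
  expect_lt(max(abs(glob$sigma[seg] - pair$sigma[seg])) /
              consistent_chain$sigma_o, 0.01)
})

test_that("fully TnI-pinned strand pins every seventh site", {
  n <- 140L
  ts <- tni_sites(n)
  pr <- pinning_profile(n, ts, rep("tni", length(ts)))
  sol <- chain_solution(pr, consistent_chain)
  expect_equal(sol$phi_bar[ts], rep(-25, length(ts)))
  expect_equal(sol$sigma[ts], rep(0, length(ts)))
  between <- setdiff(ts[3]:ts[10], ts)
  expect_true(all(abs(sol$phi_bar[between]) < 25))
  expect_true(all(sol$phi_bar[between] < 0))
})

test_that("chain energy is zero for the free chain and positive when pinned", {
  expect_equal(attr(chain_solution(pinning_profile(60), consistent_chain),
                    "energy"), 0)
  e <- attr(chain_solution(pinning_profile(60, 30, "tni"), consistent_chain),
            "energy")
  expect_gt(e, 0)
})

test_that("incremental update equals a full re-solve", {
  n <- 700L
  ts <- tni_sites(n)
  set.seed(4)
  keep <- sort(sample(ts, 60))
  myo <- sort(sample(setdiff(seq_len(n), keep), 25))
  sites <- sort(c(keep, myo))
  kinds <- ifelse(sites %in% keep, "tni", "myosin")
  pr <- pinning_profile(n, sites, kinds)
  sol <- chain_solution(pr, consistent_chain)

  # no changes: identical object
  expect_identical(update_chain_solution(sol, pr, consistent_chain), sol)

  # add one strong-myosin pin mid-strand
  add <- 349L
  stopifnot(!(add %in% sites))
  s2 <- sort(c(sites, add))
  k2 <- c(kinds, "myosin")[order(c(sites, add))]
  pr2 <- pinning_profile(n, s2, k2)
  up <- update_chain_solution(sol, pr2, consistent_chain)
  full <- chain_solution(pr2, consistent_chain)
  expect_lt(max(abs(up$phi_bar - full$phi_bar)) / 25, 1e-8)
  expect_lt(max(abs(up$sigma - full$sigma)) / consistent_chain$sigma_o, 1e-8)

  # remove a pin
  drop <- which(s2 == keep[30])
  pr3 <- pinning_profile(n, s2[-drop], k2[-drop])
  up3 <- update_chain_solution(up, pr3, consistent_chain)
  full3 <- chain_solution(pr3, consistent_chain)
  expect_lt(max(abs(up3$phi_bar - full3$phi_bar)) / 25, 1e-8)
  expect_lt(max(abs(up3$sigma - full3$sigma)) / consistent_chain$sigma_o, 1e-8)

  # removing the only pin restores the free chain
  pr_one <- pinning_profile(200L, 100L, "tni")
  sol_one <- chain_solution(pr_one, consistent_chain)
  up_free <- update_chain_solution(sol_one, pinning_profile(200L),
                                   consistent_chain)
  expect_equal(up_free$phi_bar, rep(0, 200L), tolerance = 1e-10)
})

test_that("compiled solver agrees with the reference solver", {
  n <- 210L
  set.seed(9)
  sites <- sort(sample(2:(n - 1), 18))
  kinds <- sample(c("tni", "myosin"), 18, replace = TRUE)
  pr <- pinning_profile(n, sites, kinds)
  ref <- chain_solution(pr, consistent_chain)
  pk <- integer(n)
  pk[sites] <- ifelse(kinds == "tni", 1L, 2L)
  cpx <- cfcsim:::cpp_chain_sites(pk, cfcsim:::chain_cpp_list(consistent_chain), 4L)
  expect_equal(cpx$phi_bar, ref$phi_bar, tolerance = 1e-8)
  expect_equal(cpx$sigma, ref$sigma, tolerance = 1e-8)
})

test_that("chain solutions export as delimited text", {
  sol <- chain_solution(pinning_profile(30, 10, "tni"), consistent_chain)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_chain_solution(sol, path)
  back <- read.delim(path)
  expect_equal(names(back), c("site_index", "phi_bar_deg", "sigma_deg"))
  expect_equal(back$phi_bar_deg, sol$phi_bar)
})
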