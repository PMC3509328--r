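# shared fixtures: parameter sets, small configurations, ODE oracle

tbl_params <- default_params()

# self-consistent chain parameters (identities exact, not the rounded
# published set): kappa and xi as published, everything else derived
consistent_chain <- chain_params(kappa = 2e4, xi = 1 / 22.2,
                                 phi_minus = -25, phi_plus = 10,
                                 kBT = 4.045)

small_config <- function(duration = 0.05, n_strands = 20L, n_sites = 140L,
                         a_tot = 0.5e-6, m_tot = 5e-6, dt = 1e-5,
                         burn_in = 0.02, seed = 1L, ...) {
  sim_config(duration = duration, a_tot = a_tot, m_tot = m_tot,
             n_strands = n_strands, n_sites = n_sites, dt = dt,
             burn_in = burn_in, seed = seed, ...)
}

rates_kb <- function(k_b, base = tbl_params$rates) {
  r <- base
  r$k_tni_off <- k_b * base$k_tni_on
  r$K_B <- k_b
  r$K_I <- 1 / k_b
  r
}

# two-step mass-action binding with myosin depletion and crowding; the
# continuum limit of the unregulated engine
ode_two_step <- function(times, rates, m_tot, a_tot) {
  fn <- function(t, y, p) {
    f <- y[1] + y[2]
    m <- max(m_tot - f * a_tot, 0)
    delta <- 1 - 0.82 * f
    dw <- delta * rates$k_on_weak_2nd * m * (1 - f) -
      rates$k_off_weak * y[1] - rates$k_iso_fwd * y[1] +
      rates$k_iso_rev * y[2]
    ds <- rates$k_iso_fwd * y[1] - rates$k_iso_rev * y[2]
    list(c(dw, ds))
  }
  deSolve::ode(c(w = 0, s = 0), times, fn, NULL,
               rtol = 1e-10, atol = 1e-12)
}

# closed-form mean-angle decay away from a single pin on a long chain
single_pin_profile <- function(s_abs, xi) {
  exp(-xi * s_abs) * (cos(xi * s_abs) + sin(xi * s_abs))
}
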