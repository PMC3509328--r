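# Gaussian-tail probability 1/2 erfc(x / sqrt(2)) with exact sigma -> 0 limits
half_erfc_scaled <- function(num_deg, sigma_deg) {
  out <- numeric(length(num_deg))
  num_deg <- rep_len(num_deg, length(out))
  sigma_deg <- rep_len(sigma_deg, length(out))
  pos <- sigma_deg > 0
  out[pos] <- stats::pnorm(num_deg[pos] / sigma_deg[pos], lower.tail = FALSE)
  z <- !pos
  out[z] <- ifelse(num_deg[z] < 0, 1, ifelse(num_deg[z] == 0, 0.5, 0))
  out
}

#' Chain weight for TnI rebinding
#'
#' Probability that the fluctuating chain lies in the blocked angular range
#' `phi <= phi_minus`, given the local mean angle and SD:
#' `r_I = 1/2 erfc((phi_bar - phi_minus) / (sqrt(2) sigma))`. In the
#' `sigma -> 0` limit this is 1, 1/2 or 0 according to whether `phi_bar`
#' lies below, at, or above the pinning angle.
#'
#' @param phi_bar local mean chain angle (degrees); vectorized.
#' @param sigma local chain SD (degrees, >= 0); vectorized.
#' @param phi_minus TnI pinning angle (degrees, negative).
#' @return weight in \[0, 1\].
#' @export
weight_tni_rebind <- function(phi_bar, sigma, phi_minus) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  half_erfc_scaled(phi_bar - phi_minus, sigma)
}

#' Chain weight for myosin binding and isomerization
#'
#' Probability that the chain lies at or beyond `threshold`:
#' `r = 1/2 erfc((threshold - phi_bar) / (sqrt(2) sigma))`. Use
#' `threshold = phi_o` for weak binding (giving the closed-state normalizer
#' `r_M1^o = 1/2`) and `threshold = phi_plus` for the weak-to-strong
#' isomerization.
#'
#' @param phi_bar local mean chain angle (degrees); vectorized.
#' @param sigma local chain SD (degrees, >= 0); vectorized.
#' @param threshold angular threshold (degrees).
#' @return weight in \[0, 1\].
#' @export
weight_myosin <- function(phi_bar, sigma, threshold) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  half_erfc_scaled(threshold - phi_bar, sigma)
}

#' Effective chain-regulated TnI rebinding rate
#'
#' `k_I(s_i) = (r_I / r_I^o) k_I^o`, where `r_I^o` is the weight evaluated at
#' the unconstrained closed-state distribution `(phi_o, sigma_o)`.
#'
#' @param r_i local rebinding weight.
#' @param r_i_o closed-state normalizer (must be positive, which requires
#'   `phi_minus` below `phi_o`).
#' @param k_tni_on closed-state TnI binding rate (1/s).
#' @return effective rate (1/s).
#' @export
effective_tni_on <- function(r_i, r_i_o, k_tni_on) {
  if (any(r_i_o <= 0))
    stop("closed-state rebinding weight is zero: phi_minus must lie below phi_o")
  (r_i / r_i_o) * k_tni_on
}

#' Effective chain-regulated myosin rates
#'
#' `k_M1(s_i) = (r_M1 / r_M1^o) k_M1^o [M]` (1/s, first order in the free
#' myosin concentration) and `k_M2(s_i) = (r_M2 / r_M2^o) k_M2^o`.
#'
#' @param r_m1,r_m2 local weights from [weight_myosin].
#' @param rates a [rate_constants] object.
#' @param m_free free myosin-S1 concentration (molar).
#' @param r_m1_o,r_m2_o closed-state normalizers; `r_m1_o` is 1/2 by
#'   construction, `r_m2_o` is `weight_myosin(phi_o, sigma_o, phi_plus)`.
#' @return list with `k_m1` and `k_m2` (1/s).
#' @export
effective_myosin_rates <- function(r_m1, r_m2, rates, m_free,
                                   r_m1_o = 0.5, r_m2_o) {
  if (m_free < 0) stop("free myosin concentration must be non-negative")
  if (r_m1_o <= 0 || r_m2_o <= 0) stop("closed-state normalizers must be positive")
  list(k_m1 = (r_m1 / r_m1_o) * rates$k_on_weak_2nd * m_free,
       k_m2 = (r_m2 / r_m2_o) * rates$k_iso_fwd)
}

#' Crowding factor for weak myosin binding
#'
#' Empirical linear slowing of weak binding with ensemble occupancy:
#' `delta = 1 - 0.82 (n_AM / n_A)`, ranging from 1 (empty) down to 0.18
#' (saturated). Applied only to the weak-binding step.
#'
#' @param n_am number of actin sites carrying bound myosin (weak or strong).
#' @param n_a total number of actin sites.
#' @return delta in \[0.18, 1\].
#' @export
crowding_delta <- function(n_am, n_a) {
  if (any(n_am < 0) || any(n_am > n_a)) stop("require 0 <= n_am <= n_a")
  1 - 0.82 * (n_am / n_a)
}

#' Free myosin concentration under depletion
#'
#' `[M] = [M_tot] - f [A_tot]`, where `f` is the fraction of actin sites
#' occupied by myosin (weak or strong). Floored at zero with a warning when
#' depletion exceeds the supply.
#'
#' @param f fraction of occupied actin sites, in \[0, 1\].
#' @param m_tot total myosin-S1 concentration (molar).
#' @param a_tot total actin monomer concentration (molar).
#' @return free myosin concentration (molar).
#' @export
free_myosin_conc <- function(f, m_tot, a_tot) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  if (m_tot < 0 || a_tot < 0) stop("concentrations must be non-negative")
  m <- m_tot - f * a_tot
  if (any(m < 0)) {
    warning("myosin depletion exceeds supply; free concentration floored at 0")
    m <- pmax(m, 0)
  }
  m
}

#' Per-step transition probability bins
#'
#' Converts the chain state of a strand into the per-site Monte Carlo
#' transition probabilities for one timestep: TnI detachment/rebinding at
#' the regulatory sites and the free/weak/strong myosin transitions at every
#' actin site. Weak binding is possible only at free sites, isomerization
#' only at weak sites, reverse isomerization only at strong sites, and TnI
#' rebinding is forbidden while any myosin occupies the same monomer. The
#' crowding factor applies only to weak binding. This is the reference
#' (R-level) construction mirrored by the compiled simulation engine.
#'
#' @param solution a [chain_solution] for the strand.
#' @param site_state integer vector (0 free, 1 weak, 2 strong) per site.
#' @param tni_bound logical vector per regulatory site.
#' @param tni_sites integer vector of regulatory site indices.
#' @param params a [chain_params] object.
#' @param rates a [rate_constants] object.
#' @param dt timestep (s).
#' @param m_free free myosin concentration (molar).
#' @param delta crowding factor.
#' @return list with data.frames `sites` (columns `site`, `p_m1`, `p_mm1`,
#'   `p_m2`, `p_mm2`) and `tni` (columns `site`, `p_i`, `p_mi`); bins not
#'   available from the current state are zero.
#' @export
transition_probs <- function(solution, site_state, tni_bound, tni_sites,
                             params, rates, dt, m_free, delta = 1) {
  if (dt <= 0) stop("dt must be positive")
  r_i_o <- weight_tni_rebind(params$phi_o, params$sigma_o, params$phi_minus)
  r_m2_o <- weight_myosin(params$phi_o, params$sigma_o, params$phi_plus)
  r_m1 <- weight_myosin(solution$phi_bar, solution$sigma, params$phi_o)
  r_m2 <- weight_myosin(solution$phi_bar, solution$sigma, params$phi_plus)
  km <- effective_myosin_rates(r_m1, r_m2, rates, m_free, r_m2_o = r_m2_o)
  p_m1 <- ifelse(site_state == 0L, delta * km$k_m1 * dt, 0)
  p_m2 <- ifelse(site_state == 1L, km$k_m2 * dt, 0)
  p_mm1 <- ifelse(site_state == 1L, rates$k_off_weak * dt, 0)
  p_mm2 <- ifelse(site_state == 2L, rates$k_iso_rev * dt, 0)

  r_i <- weight_tni_rebind(solution$phi_bar[tni_sites],
                           solution$sigma[tni_sites], params$phi_minus)
  occupied <- site_state[tni_sites] != 0L
  p_i <- ifelse(!tni_bound & !occupied,
                effective_tni_on(r_i, r_i_o, rates$k_tni_on) * dt, 0)
  p_mi <- ifelse(tni_bound, rates$k_tni_off * dt, 0)

  bins <- c(p_m1, p_m2 + p_mm1, p_mm2, p_i, p_mi)
  if (any(bins > 1))
    stop("timestep too large: a transition probability bin exceeds 1")
  if (max(bins) > 0.05)
    warning(sprintf(
      "largest transition probability per step is %.3g (> 0.05); consider a smaller dt",
      max(bins)))
  list(sites = data.frame(site = seq_along(site_state), p_m1 = p_m1,
                          p_mm1 = p_mm1, p_m2 = p_m2, p_mm2 = p_mm2),
       tni = data.frame(site = tni_sites, p_i = p_i, p_mi = p_mi))
}
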