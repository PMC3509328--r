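#' Mechanical parameters of the confined tropomyosin-troponin chain
#'
#' Constructs and validates the parameter set of the confined flexible-chain
#' model: bending stiffness, confining-potential strength, inverse persistence
#' length, free-chain angular fluctuation, and the three characteristic
#' azimuthal angles (blocked, closed, open). Angles are degrees at the
#' interface; all energy/variance arithmetic is done in radians internally.
#'
#' At least `kappa` and one of `xi` or `alpha` must be given; the remaining
#' quantities are derived from the identities `xi = (alpha/(4 kappa))^(1/4)`
#' and `sigma_o = (kBT/(8 kappa xi^3))^(1/2)`. If `alpha` or `sigma_o` are
#' supplied in addition, they are checked against the derived values at
#' relative tolerance `tol` (published parameter tables carry rounding, so
#' pass a loose `tol` for those).
#'
#' @param kappa angular bending stiffness per unit length (pN nm^4).
#' @param xi inverse persistence length of the confined chain (1/nm).
#' @param alpha confining-potential strength (pN).
#' @param sigma_o free-chain angular standard deviation (degrees).
#' @param phi_minus TnI pinning angle (degrees, negative).
#' @param phi_plus strong-myosin pinning angle (degrees, positive).
#' @param monomer_spacing axial actin monomer spacing (nm).
#' @param kBT thermal energy (pN nm); default 4.045 corresponds to 293 K.
#' @param tol relative tolerance for consistency of supplied derived values.
#' @return an object of class `chain_params`: a list with fields `kappa`,
#'   `alpha`, `xi`, `sigma_o` (degrees), `sigma_o_rad`, `phi_minus`,
#'   `phi_plus`, `phi_o` (always 0), `monomer_spacing`, `kBT`.
#' @export
chain_params <- function(kappa, xi = NULL, alpha = NULL, sigma_o = NULL,
                         phi_minus = -25, phi_plus = 10,
                         monomer_spacing = 5.5, kBT = 4.045, tol = 1e-9) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L)
  if (kappa <= 0) stop("kappa must be positive")
  if (kBT <= 0) stop("kBT must be positive")
  if (monomer_spacing <= 0) stop("monomer_spacing must be positive")
  if (!(phi_minus < 0 && 0 < phi_plus))
    stop("pinning angles must satisfy phi_minus < phi_o = 0 < phi_plus")
  if (is.null(xi) && is.null(alpha))
    stop("one of xi or alpha is required")
  if (is.null(xi)) {
    if (alpha <= 0) stop("alpha must be positive")
    xi <- (alpha / (4 * kappa))^0.25
  } else if (xi <= 0) stop("xi must be positive")
  alpha_d <- derive_alpha(kappa, xi)
  if (!is.null(alpha) && abs(alpha - alpha_d) > tol * alpha_d)
    stop(sprintf("alpha inconsistent with xi: given %.6g, identity gives %.6g",
                 alpha, alpha_d))
  sig_rad <- sqrt(kBT / (8 * kappa * xi^3))
  sig_deg <- sig_rad * 180 / pi
  if (!is.null(sigma_o) && abs(sigma_o - sig_deg) > tol * sig_deg)
    stop(sprintf(
      "sigma_o inconsistent with kappa, xi, kBT: given %.6g deg, identity gives %.6g deg",
      sigma_o, sig_deg))
  out <- list(kappa = kappa, alpha = alpha_d, xi = xi,
              sigma_o = if (is.null(sigma_o)) sig_deg else sigma_o,
              sigma_o_rad = sig_rad,
              phi_minus = phi_minus, phi_plus = phi_plus, phi_o = 0,
              monomer_spacing = monomer_spacing, kBT = kBT)
  class(out) <- "chain_params"
  out
}

#' @export
print.chain_params <- function(x, ...) {
  cat("Confined flexible-chain parameters\n")
  cat(sprintf("  kappa   %.4g pN nm^4   (bending stiffness per unit length)\n", x$kappa))
  cat(sprintf("  alpha   %.4g pN        (confining potential strength)\n", x$alpha))
  cat(sprintf("  1/xi    %.4g nm        (confined persistence length)\n", 1 / x$xi))
  cat(sprintf("  sigma_o %.4g deg       (free-chain angular SD)\n", x$sigma_o))
  cat(sprintf("  phi_-/phi_o/phi_+  %g / %g / %g deg\n",
              x$phi_minus, x$phi_o, x$phi_plus))
  cat(sprintf("  monomer spacing %.3g nm, kBT %.4g pN nm\n",
              x$monomer_spacing, x$kBT))
  invisible(x)
}

#' Chain bending stiffness from the solution persistence length
#'
#' The angular bending stiffness per unit length of the chain on the filament
#' is `kappa = kappa_TmTn * R^2`, where `kappa_TmTn = Lp_TmTn * kBT` is the
#' bending stiffness of the free tropomyosin-troponin chain in solution and
#' `R` is the radius at which tropomyosin sits on the actin filament.
#'
#' @param Lp_TmTn persistence length of the Tm-Tn chain in solution (nm).
#' @param R radius of tropomyosin on actin (nm).
#' @param kBT thermal energy (pN nm).
#' @return list with `kappa` (pN nm^4) and the intermediate `kappa_TmTn`
#'   (pN nm^2).
#' @export
derive_chain_stiffness <- function(Lp_TmTn, R = 4.5, kBT = 4.045) {
  if (any(c(Lp_TmTn, R, kBT) <= 0))
    stop("Lp_TmTn, R and kBT must all be positive")
  kTmTn <- Lp_TmTn * kBT
  list(kappa = kTmTn * R^2, kappa_TmTn = kTmTn)
}

#' Free-chain angular SD from the blocked-state fraction
#'
#' With the free chain fluctuating as N(0, sigma_o) about the closed angle,
#' requiring that a fraction `blocked_fraction` of the chain lies at or below
#' the TnI pinning angle -|phi_minus_abs| gives
#' `sigma_o = phi_minus_abs / |qnorm(blocked_fraction)|`.
#'
#' @param phi_minus_abs magnitude of the TnI pinning angle (degrees, > 0).
#' @param blocked_fraction fraction of the free chain in the blocked range,
#'   strictly between 0 and 0.5.
#' @return sigma_o in degrees.
#' @export
derive_sigma_free <- function(phi_minus_abs, blocked_fraction) {
  if (phi_minus_abs <= 0) stop("phi_minus_abs must be positive")
  if (blocked_fraction <= 0 || blocked_fraction >= 0.5)
    stop("blocked_fraction must lie strictly between 0 and 0.5")
  phi_minus_abs / abs(stats::qnorm(blocked_fraction))
}

#' Inverse persistence length from the free-chain angular SD
#'
#' Inverts `sigma_o = (kBT/(8 kappa xi^3))^(1/2)` for `xi`.
#'
#' @param kappa bending stiffness (pN nm^4).
#' @param sigma_o free-chain angular SD in degrees.
#' @param kBT thermal energy (pN nm).
#' @return xi in 1/nm.
#' @export
derive_xi <- function(kappa, sigma_o, kBT = 4.045) {
  if (any(c(kappa, sigma_o, kBT) <= 0))
    stop("kappa, sigma_o and kBT must all be positive")
  s <- sigma_o * pi / 180
  (kBT / (8 * kappa * s^2))^(1 / 3)
}

#' Confining-potential strength from the identity alpha = 4 kappa xi^4
#'
#' @param kappa bending stiffness (pN nm^4).
#' @param xi inverse persistence length (1/nm).
#' @return alpha in pN.
#' @export
derive_alpha <- function(kappa, xi) {
  if (kappa <= 0 || xi < 0) stop("kappa must be positive and xi non-negative")
  4 * kappa * xi^4
}

#' Kinetic rate constants of the regulation scheme
#'
#' Unregulated rate constants for two-step myosin-S1 binding (weak
#' attachment, weak-to-strong isomerization) and for TnI-actin binding,
#' plus the calcium-dependent TnI detachment rate. The derived equilibrium
#' constants `K_B = k_tni_off / k_tni_on` (and `K_I = 1/K_B`) are attached
#' read-only; `K_B` is the single calcium-dependent quantity of the model.
#'
#' @param k_on_weak_2nd second-order weak-binding rate constant (1/M/s).
#' @param k_off_weak weak-myosin detachment rate (1/s).
#' @param k_iso_fwd weak-to-strong isomerization rate from the closed state (1/s).
#' @param k_iso_rev reverse isomerization rate (1/s).
#' @param k_tni_on TnI-actin binding rate from the closed state (1/s).
#' @param k_tni_off TnI-actin detachment rate, calcium dependent (1/s).
#' @return object of class `rate_constants`.
#' @export
rate_constants <- function(k_on_weak_2nd = 4.2e6, k_off_weak = 20,
                           k_iso_fwd = 500, k_iso_rev = 5,
                           k_tni_on = 100, k_tni_off = 1200) {
  v <- c(k_on_weak_2nd, k_off_weak, k_iso_fwd, k_iso_rev, k_tni_on, k_tni_off)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all rate constants must be finite and non-negative")
  out <- list(k_on_weak_2nd = k_on_weak_2nd, k_off_weak = k_off_weak,
              k_iso_fwd = k_iso_fwd, k_iso_rev = k_iso_rev,
              k_tni_on = k_tni_on, k_tni_off = k_tni_off,
              K_B = if (k_tni_on > 0) k_tni_off / k_tni_on else Inf,
              K_I = if (k_tni_off > 0) k_tni_on / k_tni_off else Inf)
  class(out) <- "rate_constants"
  out
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Regulation rate constants\n")
  cat(sprintf("  weak binding  k_M1^o %.3g /M/s, detachment k_-M1 %.3g /s\n",
              x$k_on_weak_2nd, x$k_off_weak))
  cat(sprintf("  isomerization k_M2^o %.3g /s, reverse k_-M2 %.3g /s\n",
              x$k_iso_fwd, x$k_iso_rev))
  cat(sprintf("  TnI binding   k_I^o  %.3g /s, detachment k_-I %.3g /s\n",
              x$k_tni_on, x$k_tni_off))
  cat(sprintf("  K_B = k_-I/k_I^o = %.4g (K_I = %.4g)\n", x$K_B, x$K_I))
  invisible(x)
}

#' Published default parameter set
#'
#' The full published parameter set of the model: `phi_- = -25` deg,
#' `phi_+ = 10` deg, `kappa = 2.0e4` pN nm^4, `1/xi = 22.2` nm,
#' `sigma_o = 29.7` deg, `alpha = 0.341` pN, and the rates
#' `k_M1^o = 4.2e6` /M/s, `k_-M1 = 20` /s, `k_M2^o = 500` /s,
#' `k_-M2 = 5` /s, `k_I^o = 100` /s, `k_-I = 1200` /s (high calcium).
#' The printed values carry rounding, so the internal-consistency identities
#' are checked at 5 per cent rather than machine tolerance.
#'
#' @param kBT thermal energy (pN nm).
#' @return list with components `chain` (a [chain_params] object) and
#'   `rates` (a [rate_constants] object).
#' @export
default_params <- function(kBT = 4.045) {
  chain <- chain_params(kappa = 2.0e4, xi = 1 / 22.2,
                        alpha = 0.341, sigma_o = 29.7,
                        phi_minus = -25, phi_plus = 10,
                        kBT = kBT, tol = 0.05)
  list(chain = chain, rates = rate_constants())
}

# angle helpers, centralized degree <-> radian conversion
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Write / read a parameter set as flat key = value text
#'
#' Keys follow the symbols of the published parameter table:
#' `phi_minus_deg`, `phi_plus_deg`, `kappa_pN_nm4`, `alpha_pN`, `inv_xi_nm`,
#' `sigma_o_deg`, `kBT_pN_nm`, `monomer_spacing_nm`, `k_M1_o_per_M_s`,
#' `k_mM1_per_s`, `k_M2_o_per_s`, `k_mM2_per_s`, `k_I_o_per_s`, `k_mI_per_s`.
#'
#' @param params list with `chain` and `rates` components as returned by
#'   [default_params].
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   list with `chain` and `rates`.
#' @export
write_params <- function(params, path) {
  ch <- params$chain; ra <- params$rates
  kv <- c(phi_minus_deg = ch$phi_minus, phi_plus_deg = ch$phi_plus,
          kappa_pN_nm4 = ch$kappa, alpha_pN = ch$alpha,
          inv_xi_nm = 1 / ch$xi, sigma_o_deg = ch$sigma_o,
          kBT_pN_nm = ch$kBT, monomer_spacing_nm = ch$monomer_spacing,
          k_M1_o_per_M_s = ra$k_on_weak_2nd, k_mM1_per_s = ra$k_off_weak,
          k_M2_o_per_s = ra$k_iso_fwd, k_mM2_per_s = ra$k_iso_rev,
          k_I_o_per_s = ra$k_tni_on, k_mI_per_s = ra$k_tni_off)
  writeLines(sprintf("%s = %.15g", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  kv <- read_config(path)
  need <- function(k) {
    if (is.null(kv[[k]])) stop("missing parameter key: ", k)
    as.numeric(kv[[k]])
  }
  chain <- chain_params(kappa = need("kappa_pN_nm4"),
                        xi = 1 / need("inv_xi_nm"),
                        alpha = need("alpha_pN"),
                        sigma_o = need("sigma_o_deg"),
                        phi_minus = need("phi_minus_deg"),
                        phi_plus = need("phi_plus_deg"),
                        monomer_spacing = need("monomer_spacing_nm"),
                        kBT = need("kBT_pN_nm"), tol = 0.05)
  rates <- rate_constants(k_on_weak_2nd = need("k_M1_o_per_M_s"),
                          k_off_weak = need("k_mM1_per_s"),
                          k_iso_fwd = need("k_M2_o_per_s"),
                          k_iso_rev = need("k_mM2_per_s"),
                          k_tni_on = need("k_I_o_per_s"),
                          k_tni_off = need("k_mI_per_s"))
  list(chain = chain, rates = rates)
}
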