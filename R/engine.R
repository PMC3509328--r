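#' Simulation configuration
#'
#' Bundles the ensemble geometry, concentrations, timestep and bookkeeping
#' options of a fixed-timestep Monte Carlo run. Each simulated subsystem is
#' one strand of an actin double helix carrying one regulated chain, with a
#' regulatory (TnI) site at every seventh monomer starting from the third;
#' two strands per filament are simulated as independent subsystems.
#'
#' @param duration simulated time after mixing with myosin (s).
#' @param a_tot total actin monomer concentration (molar).
#' @param m_tot total myosin-S1 concentration (molar).
#' @param n_strands number of strands (must be even; 2000 suits
#'   excess-actin conditions, 200 excess-myosin).
#' @param n_sites actin monomers per strand (700 gives a 3.85 um filament).
#' @param dt Monte Carlo timestep (s).
#' @param burn_in duration of TnI-only equilibration before myosin is made
#'   available (s); 0 starts cold with every TnI bound.
#' @param record_every recording interval in steps.
#' @param seed integer seed for the engine's random stream.
#' @param use_chain logical; FALSE disables all chain regulation (weights
#'   fixed at their closed-state values, no pinning), giving unregulated
#'   mass-action kinetics for limit checks.
#' @param refine sub-monomer grid refinement of the chain solver.
#' @param window_sites half-width (in sites) of the chain re-solve window
#'   around a pin change.
#' @param margin_sites sites discarded next to a clamped window edge when
#'   accepting recomputed fluctuation values.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(duration, a_tot, m_tot, n_strands = 2000L,
                       n_sites = 700L, dt = 1e-5, burn_in = 0.5,
                       record_every = 100L, seed = 1L, use_chain = TRUE,
                       refine = 4L, window_sites = 32L, margin_sites = 14L) {
  if (duration < 0) stop("duration must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (a_tot < 0 || m_tot < 0) stop("concentrations must be non-negative")
  if (n_strands < 2L || n_strands %% 2L != 0L)
    stop("n_strands must be even (two strands per filament)")
  if (n_sites < 10L) stop("n_sites too small")
  if (burn_in < 0) stop("burn_in must be non-negative")
  if (record_every < 1L) stop("record_every must be >= 1")
  if (margin_sites >= window_sites) stop("margin_sites must be < window_sites")
  structure(list(duration = duration, a_tot = a_tot, m_tot = m_tot,
                 n_strands = as.integer(n_strands),
                 n_sites = as.integer(n_sites), dt = dt, burn_in = burn_in,
                 record_every = as.integer(record_every),
                 seed = as.integer(seed), use_chain = isTRUE(use_chain),
                 refine = as.integer(refine),
                 window_sites = as.integer(window_sites),
                 margin_sites = as.integer(margin_sites)),
            class = "sim_config")
}

#' Regulatory-site positions of a strand
#'
#' TnI sites sit at every seventh monomer starting from the third.
#'
#' @param n_sites number of monomers in the strand.
#' @return integer vector of 1-based site indices.
#' @export
tni_sites <- function(n_sites) seq(3L, n_sites, by = 7L)

chain_cpp_list <- function(params) {
  list(kappa = params$kappa, alpha = params$alpha, kBT = params$kBT,
       phi_minus_rad = deg2rad(params$phi_minus),
       phi_plus_rad = deg2rad(params$phi_plus),
       sigma_o_rad = params$sigma_o_rad,
       monomer_spacing = params$monomer_spacing,
       r_i_o = weight_tni_rebind(params$phi_o, params$sigma_o, params$phi_minus),
       r_m2_o = weight_myosin(params$phi_o, params$sigma_o, params$phi_plus))
}

config_cpp_list <- function(config) {
  config[c("n_sites", "n_strands", "dt", "a_tot", "m_tot", "use_chain",
           "refine", "window_sites", "margin_sites")]
}

check_bins <- function(config, params, rates) {
  cl <- chain_cpp_list(params)
  worst <- c(p_i = rates$k_tni_on * config$dt / cl$r_i_o,
             p_mi = rates$k_tni_off * config$dt,
             p_m1 = 2 * rates$k_on_weak_2nd * config$m_tot * config$dt,
             p_mm1 = rates$k_off_weak * config$dt,
             p_m2 = rates$k_iso_fwd * config$dt / cl$r_m2_o,
             p_mm2 = rates$k_iso_rev * config$dt)
  w2 <- worst[c("p_m2", "p_mm1")]
  if (max(worst["p_m1"], sum(w2), worst[c("p_i", "p_mi", "p_mm2")]) > 1)
    stop("timestep too large: a transition probability bin can exceed 1")
  if (max(worst) > 0.05)
    warning(sprintf(
      "largest per-step transition probability may reach %.3g (> 0.05); consider reducing dt",
      max(worst)))
  invisible(worst)
}

#' Initialize and equilibrate an ensemble
#'
#' Creates an ensemble of strands with every actin site free and every TnI
#' bound, then equilibrates the TnI occupancy by running the TnI-only
#' dynamics (no myosin present) for `burn_in` seconds at the configured
#' calcium-dependent detachment rate. At the returned state (time 0) myosin
#' becomes available.
#'
#' @param config a [sim_config].
#' @param params a [chain_params] object.
#' @param rates a [rate_constants] object.
#' @return an ensemble-state object of class `cfc_ensemble` (site states,
#'   TnI flags, simulation time, and the engine's RNG state).
#' @export
init_ensemble <- function(config, params, rates) {
  check_bins(config, params, rates)
  n_tni <- length(tni_sites(config$n_sites))
  st <- list(site_state = matrix(0L, config$n_sites, config$n_strands),
             tni_bound = matrix(1L, n_tni, config$n_strands),
             time = 0, rng_state = cpp_rng_state(config$seed))
  n_burn <- round(config$burn_in / config$dt)
  if (n_burn > 0) {
    res <- cpp_run(st, chain_cpp_list(params), unclass(rates),
                   config_cpp_list(config), as.integer(n_burn), 0L,
                   integer(), TRUE)
    st <- res$state
    st$time <- 0
  }
  class(st) <- "cfc_ensemble"
  st
}

#' Advance an ensemble by Monte Carlo steps
#'
#' Runs the two-drawing fixed-timestep scheme: one drawing over the
#' regulatory sites (TnI detachment/rebinding), one over all actin sites
#' (free/weak/strong myosin transitions), with the chain solution refreshed
#' after every pin change.
#'
#' @param state a `cfc_ensemble` from [init_ensemble] or a previous call.
#' @inheritParams init_ensemble
#' @param n_steps number of timesteps to advance.
#' @return the updated `cfc_ensemble`.
#' @export
mc_step <- function(state, config, params, rates, n_steps = 1L) {
  res <- cpp_run(unclass(state), chain_cpp_list(params), unclass(rates),
                 config_cpp_list(config), as.integer(n_steps), 0L,
                 integer(), FALSE)
  structure(res$state, class = "cfc_ensemble")
}

#' Simulate a binding transient
#'
#' Initializes and equilibrates the ensemble, then simulates
#' `duration/dt` steps of myosin binding, recording the ensemble composition
#' at the configured interval. The recorded `frac_not_R` — the fraction of
#' actin sites not strongly bound (not in the R-state) — is the model's
#' proxy for normalized pyrene fluorescence.
#'
#' @inheritParams init_ensemble
#' @param snapshot_times numeric vector of times (s) at which to capture
#'   full per-site occupancy and chain-state snapshots.
#' @param state optional pre-built ensemble (skips initialization).
#' @return object of class `cfc_transient`: a data.frame with columns
#'   `time`, `frac_not_R`, `frac_weak`, `frac_strong`, `frac_tni`, `M_free`,
#'   with the final ensemble state, snapshots and configuration attached as
#'   attributes.
#' @export
run_transient <- function(config, params, rates, snapshot_times = NULL,
                          state = NULL) {
  if (is.null(state)) state <- init_ensemble(config, params, rates)
  n_steps <- as.integer(round(config$duration / config$dt))
  snap_steps <- integer()
  if (!is.null(snapshot_times)) {
    snap_steps <- sort(unique(pmin(pmax(
      as.integer(round(snapshot_times / config$dt)), 0L), n_steps)))
  }
  res <- cpp_run(unclass(state), chain_cpp_list(params), unclass(rates),
                 config_cpp_list(config), n_steps, config$record_every,
                 snap_steps, FALSE)
  out <- as.data.frame(res$trace)
  if (n_steps == 0L) out <- out[0L, , drop = FALSE]
  attr(out, "state") <- structure(res$state, class = "cfc_ensemble")
  attr(out, "snapshots") <- res$snapshots
  attr(out, "config") <- config
  class(out) <- c("cfc_transient", "data.frame")
  out
}

#' @export
print.cfc_transient <- function(x, ...) {
  cat(sprintf(
    "Binding transient: %d records over %.4g s, final not-R fraction %.4g\n",
    nrow(x), max(x$time), x$frac_not_R[nrow(x)]))
  invisible(x)
}

#' Snapshots attached to a transient
#'
#' @param transient a `cfc_transient`.
#' @return list of snapshots; each has `time`, `site_state` and `tni_bound`
#'   matrices (sites/regulatory units by strand), and per-site
#'   `phi_bar_deg`, `sigma_deg` chain fields.
#' @export
transient_snapshots <- function(transient) attr(transient, "snapshots")

#' Write a transient as delimited text
#'
#' Tab-separated columns `time_s`, `frac_not_R`, `frac_weak`, `frac_strong`,
#' `frac_TnI_bound`, `M_free_molar`.
#'
#' @param transient a `cfc_transient`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transient <- function(transient, path) {
  df <- data.frame(time_s = transient$time,
                   frac_not_R = transient$frac_not_R,
                   frac_weak = transient$frac_weak,
                   frac_strong = transient$frac_strong,
                   frac_TnI_bound = transient$frac_tni,
                   M_free_molar = transient$M_free)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a snapshot as columnar text
#'
#' One row per (strand, site): columns `strand`, `site`, `state`
#' (0 free / 1 weak / 2 strong), `phi_bar_deg`, `sigma_deg`.
#'
#' @param snapshot one element of [transient_snapshots].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  n_sites <- nrow(snapshot$site_state)
  n_strands <- ncol(snapshot$site_state)
  df <- data.frame(strand = rep(seq_len(n_strands), each = n_sites),
                   site = rep(seq_len(n_sites), n_strands),
                   state = as.vector(snapshot$site_state),
                   phi_bar_deg = as.vector(snapshot$phi_bar_deg),
                   sigma_deg = as.vector(snapshot$sigma_deg))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
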