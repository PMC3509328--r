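#' Pinning configuration of one filament strand
#'
#' A pinning profile lists the actin sites at which the chain angle is fixed:
#' by actin-bound TnI at `phi_minus`, or by strongly bound myosin-S1 at
#' `phi_plus`. Site indices are 1-based monomer indices along the strand.
#'
#' @param n_sites number of actin monomers in the strand.
#' @param sites integer vector of pinned site indices (strictly increasing).
#' @param kinds character vector, one of `"tni"` or `"myosin"` per pin.
#' @return object of class `pinning_profile`.
#' @export
pinning_profile <- function(n_sites, sites = integer(), kinds = character()) {
  sites <- as.integer(sites)
  if (length(sites) != length(kinds))
    stop("sites and kinds must have the same length")
  if (length(sites)) {
    if (any(diff(sites) <= 0)) stop("pin sites must be strictly increasing")
    if (any(sites < 1L | sites > n_sites)) stop("pin outside strand")
    if (!all(kinds %in% c("tni", "myosin"))) stop("kind must be 'tni' or 'myosin'")
  }
  structure(list(n_sites = as.integer(n_sites), sites = sites,
                 kinds = as.character(kinds)),
            class = "pinning_profile")
}

pin_angles_rad <- function(profile, params) {
  ifelse(profile$kinds == "tni", deg2rad(params$phi_minus),
         deg2rad(params$phi_plus))
}

# Discretized chain energy operator K such that E = 1/2 phi' K phi with
# E = int [ kappa/2 phi''(s)^2 + alpha/2 phi(s)^2 ] ds on a uniform grid of
# spacing h with natural (free) ends: only interior curvatures enter.
chain_operator <- function(n_nodes, h, kappa, alpha) {
  i <- 2:(n_nodes - 1)
  D2 <- Matrix::sparseMatrix(
    i = rep(seq_along(i), each = 3),
    j = as.vector(rbind(i - 1L, i, i + 1L)),
    x = rep(c(1, -2, 1) / h^2, length(i)),
    dims = c(length(i), n_nodes))
  h * (kappa * Matrix::crossprod(D2) + alpha * Matrix::Diagonal(n_nodes))
}

chain_grid <- function(profile, params, refine) {
  ds <- params$monomer_spacing
  h <- ds / refine
  n_nodes <- (profile$n_sites - 1L) * refine + 1L
  list(h = h, n_nodes = n_nodes,
       site_nodes = (seq_len(profile$n_sites) - 1L) * refine + 1L,
       pin_nodes = (profile$sites - 1L) * refine + 1L)
}

solve_constrained_mean <- function(K, pin_nodes, pin_vals) {
  n <- nrow(K)
  phi <- numeric(n)
  if (length(pin_nodes) == 0L) return(phi)
  free <- setdiff(seq_len(n), pin_nodes)
  rhs <- -K[free, pin_nodes, drop = FALSE] %*% pin_vals
  phi[free] <- as.vector(Matrix::solve(K[free, free], rhs))
  phi[pin_nodes] <- pin_vals
  phi
}

# Diagonal of the inverse of a symmetric positive-definite pentadiagonal
# matrix via band LDL' and the Takahashi recurrences (exact on the band).
band_diag_inverse <- function(A) {
  n <- nrow(A)
  a0 <- Matrix::diag(A)
  a1 <- if (n > 1) A[cbind(1:(n - 1), 2:n)] else numeric(0)
  a2 <- if (n > 2) A[cbind(1:(n - 2), 3:n)] else numeric(0)
  d <- numeric(n); l1 <- numeric(n); l2 <- numeric(n)
  for (i in seq_len(n)) {
    di <- a0[i]
    if (i > 1) di <- di - d[i - 1] * l1[i - 1]^2
    if (i > 2) di <- di - d[i - 2] * l2[i - 2]^2
    d[i] <- di
    if (i < n) {
      x <- a1[i]
      if (i > 1) x <- x - d[i - 1] * l2[i - 1] * l1[i - 1]
      l1[i] <- x / di
    }
    if (i < n - 1) l2[i] <- a2[i] / di
  }
  z0 <- numeric(n); z1 <- numeric(n); z2 <- numeric(n)
  z0[n] <- 1 / d[n]
  if (n > 1) {
    z1[n - 1] <- -l1[n - 1] * z0[n]
    z0[n - 1] <- 1 / d[n - 1] - l1[n - 1] * z1[n - 1]
  }
  if (n > 2) for (i in (n - 2):1) {
    z2[i] <- -(l1[i] * z1[i + 1] + l2[i] * z0[i + 2])
    z1[i] <- -(l1[i] * z0[i + 1] + l2[i] * z1[i + 1])
    z0[i] <- 1 / d[i] - l1[i] * z1[i] - l2[i] * z2[i]
  }
  z0
}

solve_constrained_sigma2 <- function(K, pin_nodes, kBT) {
  n <- nrow(K)
  free <- if (length(pin_nodes)) setdiff(seq_len(n), pin_nodes) else seq_len(n)
  s2 <- numeric(n)
  s2[free] <- kBT * band_diag_inverse(K[free, free])
  s2
}

#' Mean chain angle field for a pinning configuration
#'
#' Minimizes the discretized chain energy subject to equality constraints at
#' the pin positions, with natural free-end boundary conditions. Between pins
#' the solution satisfies the fourth-order equilibrium equation
#' `(d^4/ds^4 + 4 xi^4) phi = 0` to discretization order; value, slope and
#' curvature are continuous across pins.
#'
#' @param profile a [pinning_profile].
#' @param params a [chain_params] object.
#' @param refine sub-monomer grid refinement factor; grid spacing is
#'   `monomer_spacing/refine` (choose so that `xi * h <= 0.1`).
#' @return list with `s` (axial positions, nm), `phi` (mean angle, degrees),
#'   and `h` (grid spacing, nm).
#' @export
solve_mean_angle <- function(profile, params, refine = 4L) {
  g <- chain_grid(profile, params, refine)
  K <- chain_operator(g$n_nodes, g$h, params$kappa, params$alpha)
  phi <- solve_constrained_mean(K, g$pin_nodes, pin_angles_rad(profile, params))
  list(s = (seq_len(g$n_nodes) - 1) * g$h, phi = rad2deg(phi), h = g$h)
}

#' Thermal standard deviation of the chain angle
#'
#' The variance at each grid node is `kBT` times the diagonal of the inverse
#' of the discretized energy operator restricted to the unpinned degrees of
#' freedom; pinned nodes have zero standard deviation. Far from pins and
#' chain ends the SD approaches the free-chain value `sigma_o`; at free ends
#' it rises above `sigma_o` (end compliance of a confined chain is larger
#' than in the bulk).
#'
#' @inheritParams solve_mean_angle
#' @return list with `s` (nm), `sigma` (degrees), and `h` (nm).
#' @export
solve_sigma <- function(profile, params, refine = 4L) {
  g <- chain_grid(profile, params, refine)
  K <- chain_operator(g$n_nodes, g$h, params$kappa, params$alpha)
  s2 <- solve_constrained_sigma2(K, g$pin_nodes, params$kBT)
  list(s = (seq_len(g$n_nodes) - 1) * g$h, sigma = rad2deg(sqrt(pmax(s2, 0))),
       h = g$h)
}

.chain_cache <- new.env(parent = emptyenv())

chain_cache_key <- function(profile, params, refine) {
  paste(profile$n_sites, refine,
        signif(params$kappa, 12), signif(params$alpha, 12),
        signif(params$kBT, 12), signif(params$monomer_spacing, 12),
        signif(params$phi_minus, 12), signif(params$phi_plus, 12),
        paste(profile$sites, substr(profile$kinds, 1, 1), collapse = ","),
        sep = "|")
}

#' Chain state at the actin sites
#'
#' Solves the mean-angle and fluctuation fields for a pinning configuration
#' and samples them at the actin-site positions (site i sits at axial
#' coordinate `(i-1) * monomer_spacing`). Solutions are cached and reused
#' for unchanged pin configurations.
#'
#' @inheritParams solve_mean_angle
#' @return object of class `chain_solution`: a data.frame with columns
#'   `site`, `s_nm`, `phi_bar` (degrees) and `sigma` (degrees), carrying the
#'   full grid fields, the profile and the total chain energy of the mean
#'   configuration (pN nm) as attributes.
#' @export
chain_solution <- function(profile, params, refine = 4L) {
  key <- chain_cache_key(profile, params, refine)
  hit <- .chain_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- chain_grid(profile, params, refine)
  K <- chain_operator(g$n_nodes, g$h, params$kappa, params$alpha)
  phi <- solve_constrained_mean(K, g$pin_nodes, pin_angles_rad(profile, params))
  s2 <- solve_constrained_sigma2(K, g$pin_nodes, params$kBT)
  sol <- build_chain_solution(profile, params, refine, g, phi, s2,
                              energy = 0.5 * sum(phi * as.vector(K %*% phi)))
  if (length(ls(.chain_cache)) > 64L) rm(list = ls(.chain_cache), envir = .chain_cache)
  .chain_cache[[key]] <- sol
  sol
}

build_chain_solution <- function(profile, params, refine, g, phi_rad, s2_rad, energy) {
  out <- data.frame(site = seq_len(profile$n_sites),
                    s_nm = (g$site_nodes - 1) * g$h,
                    phi_bar = rad2deg(phi_rad[g$site_nodes]),
                    sigma = rad2deg(sqrt(pmax(s2_rad[g$site_nodes], 0))))
  attr(out, "grid_phi") <- phi_rad
  attr(out, "grid_sigma2") <- s2_rad
  attr(out, "h") <- g$h
  attr(out, "refine") <- refine
  attr(out, "profile") <- profile
  attr(out, "energy") <- energy
  class(out) <- c("chain_solution", "data.frame")
  out
}

#' Incremental update of a chain solution after pin changes
#'
#' Recomputes the solution only on a window around each added or removed pin.
#' Clamping two adjacent grid nodes at each window edge block-separates the
#' pentadiagonal energy operator, so the recomputed mean is exact given the
#' prior field at the clamps; window sizes are chosen so that the neglected
#' exponential tails are below 1e-8 and the result equals a full re-solve to
#' that accuracy. Falls back to a full re-solve when the windows cover most
#' of the strand or the prior solution is inconsistent with its profile.
#'
#' @param solution a [chain_solution] for the previous pinning configuration.
#' @param profile the new [pinning_profile].
#' @param params a [chain_params] object.
#' @return an updated `chain_solution` for `profile`.
#' @export
update_chain_solution <- function(solution, profile, params) {
  old <- attr(solution, "profile")
  refine <- attr(solution, "refine")
  if (is.null(old) || is.null(refine) || old$n_sites != profile$n_sites)
    return(chain_solution(profile, params, refine = if (is.null(refine)) 4L else refine))
  okey <- paste(old$sites, old$kinds)
  nkey <- paste(profile$sites, profile$kinds)
  changed_sites <- c(old$sites[!(okey %in% nkey)], profile$sites[!(nkey %in% okey)])
  if (length(changed_sites) == 0L) return(solution)

  ds <- params$monomer_spacing
  w_sites <- ceiling(23 / (params$xi * ds))        # mean leak e^-23
  m_sites <- ceiling(11 / (params$xi * ds))        # sigma clamp margin e^-22
  g <- chain_grid(profile, params, refine)
  lo <- max(1L, (min(changed_sites) - 1L - w_sites) * refine + 1L)
  hi <- min(g$n_nodes, (max(changed_sites) - 1L + w_sites) * refine + 1L)
  if ((hi - lo + 1L) > 0.7 * g$n_nodes)
    return(chain_solution(profile, params, refine))

  phi <- attr(solution, "grid_phi")
  s2 <- attr(solution, "grid_sigma2")
  K <- chain_operator(g$n_nodes, g$h, params$kappa, params$alpha)
  pin_vals <- pin_angles_rad(profile, params)

  # unknown nodes: window interior, minus two clamped nodes at each edge that
  # lies strictly inside the chain, minus pinned nodes
  u_lo <- if (lo == 1L) 1L else lo + 2L
  u_hi <- if (hi == g$n_nodes) g$n_nodes else hi - 2L
  win <- u_lo:u_hi
  pins_in <- g$pin_nodes[g$pin_nodes >= u_lo & g$pin_nodes <= u_hi]
  pin_vals_in <- pin_vals[match(pins_in, g$pin_nodes)]
  unknown <- setdiff(win, pins_in)
  known <- setdiff(seq_len(g$n_nodes), unknown)
  phi[pins_in] <- pin_vals_in
  rhs <- -K[unknown, known, drop = FALSE] %*% phi[known]
  phi[unknown] <- as.vector(Matrix::solve(K[unknown, unknown], rhs))

  # sigma: conditioning on the clamps is artificial, keep only nodes at least
  # m_sites away from clamped edges; pin changes do not alter sigma beyond
  # that distance either
  s2w <- numeric(length(win))
  keep <- rep(TRUE, length(win))
  idx_un <- match(unknown, win)
  s2w[idx_un] <- params$kBT * band_diag_inverse(K[unknown, unknown])
  if (lo > 1L) keep[win < lo + m_sites * refine] <- FALSE
  if (hi < g$n_nodes) keep[win > hi - m_sites * refine] <- FALSE
  s2[win[keep]] <- s2w[keep]
  s2[pins_in] <- 0

  build_chain_solution(profile, params, refine, g, phi, s2,
                       energy = 0.5 * sum(phi * as.vector(K %*% phi)))
}

#' Export a chain solution as delimited text
#'
#' Writes tab-separated columns `site_index`, `phi_bar_deg`, `sigma_deg`.
#'
#' @param solution a [chain_solution].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_chain_solution <- function(solution, path) {
  utils::write.table(
    data.frame(site_index = solution$site,
               phi_bar_deg = solution$phi_bar,
               sigma_deg = solution$sigma),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
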