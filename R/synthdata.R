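# Synthetic-data generators with known ground truth. These emulate the
# statistical structure the downstream analyses assume (metastable jump
# dynamics, diffusive dynamics on a multi-well landscape, correlated Gaussian
# positional fluctuations, Gaussian energy components) without running MD.

#' Sample a discrete Markov jump trajectory
#'
#' Draws a state sequence from a known row-stochastic transition matrix.
#' States are labelled `1..n` (R convention). The empirical row-normalized
#' transition count matrix converges to `T` at rate `n^-1/2`.
#'
#' @param T Row-stochastic square matrix (rows sum to 1 within 1e-12,
#'   entries non-negative).
#' @param n_steps Number of jumps; the returned sequence has `n_steps + 1`
#'   labels.
#' @param initial_state Starting state in `1..nrow(T)`.
#' @param seed Integer RNG seed; the same call repeated is bit-identical.
#' @return Integer vector of length `n_steps + 1`, class `discrete_trajectory`.
#' @examples
#' T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
#' d <- sample_markov_chain(T, 100, initial_state = 1, seed = 1)
#' @export
sample_markov_chain <- function(T, n_steps, initial_state = 1L, seed) {
  check_stochastic(T)
  n <- nrow(T)
  initial_state <- as.integer(initial_state)
  if (initial_state < 1L || initial_state > n) {
    stop(sprintf("initial_state must be in 1..%d", n), call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0L)
  # cumulative rows; the last breakpoint is forced to 1 so runif never
  # falls off the end through rounding
  cum <- t(apply(T, 1L, cumsum))
  cum[, n] <- 1
  s <- integer(n_steps + 1L)
  s[1L] <- initial_state
  if (n_steps > 0L) {
    u <- with_seed(seed, runif(n_steps))
    for (t in seq_len(n_steps)) {
      s[t + 1L] <- findInterval(u[t], cum[s[t], ]) + 1L
    }
  }
  structure(s, class = c("discrete_trajectory", "integer"))
}

#' Multi-well potential specification
#'
#' Describes the energy landscape for [langevin_double_well()]. With one
#' centre the potential is harmonic, `U(x) = barrier_height/2 * |x - c|^2`
#' (so `barrier_height = 0` gives free diffusion). With two centres it is the
#' quartic double well with minima at the centres and a barrier of
#' `barrier_height` (in units of `temperature_factor`, i.e. kT) at the
#' midpoint.
#'
#' @param centers Numeric vector (1-D well centres) or matrix with one centre
#'   per row (each row a d-dimensional point, d = 1 or 2).
#' @param barrier_height Barrier height in kT units (harmonic stiffness for a
#'   single well); must be >= 0.
#' @param diffusion_coeff Positive diffusion coefficient.
#' @param temperature_factor Thermal energy kT (> 0).
#' @return An object of class `well_spec`.
#' @export
well_spec <- function(centers, barrier_height, diffusion_coeff = 1,
                      temperature_factor = 1) {
  if (is.numeric(centers) && is.null(dim(centers))) {
    centers <- matrix(centers, ncol = 1L)
  }
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("need at least one well centre", call. = FALSE)
  if (nrow(centers) > 2L) {
    stop("well_spec supports one or two well centres", call. = FALSE)
  }
  if (ncol(centers) > 2L) stop("wells must be 1-D or 2-D", call. = FALSE)
  if (barrier_height < 0) stop("barrier_height must be >= 0", call. = FALSE)
  if (diffusion_coeff <= 0) stop("diffusion_coeff must be positive", call. = FALSE)
  if (temperature_factor <= 0) stop("temperature_factor must be positive", call. = FALSE)
  structure(list(centers = centers, barrier_height = barrier_height,
                 diffusion_coeff = diffusion_coeff,
                 temperature_factor = temperature_factor),
            class = "well_spec")
}

# Potential gradient for a well_spec at positions x (matrix n x d).
well_gradient <- function(spec, x) {
  d <- ncol(spec$centers)
  h <- spec$barrier_height
  if (nrow(spec$centers) == 1L) {
    return(h * sweep(x, 2L, spec$centers[1L, ]))
  }
  c1 <- spec$centers[1L, ]; c2 <- spec$centers[2L, ]
  m <- (c1 + c2) / 2
  axis <- c2 - c1
  s <- sqrt(sum(axis^2)) / 2
  u <- axis / (2 * s)
  xm <- sweep(x, 2L, m)
  p <- drop(xm %*% u)
  # U_axis(p) = h ((p^2 - s^2)/s^2)^2 ; dU/dp = 4 h p (p^2 - s^2)/s^4
  gpar <- 4 * h * p * (p^2 - s^2) / s^4
  grad <- outer(gpar, u)
  if (d > 1L) {
    # harmonic confinement (stiffness kT) transverse to the well axis
    perp <- xm - outer(p, u)
    grad <- grad + spec$temperature_factor * perp
  }
  grad
}

#' Overdamped Langevin trajectory on a multi-well potential
#'
#' Integrates the overdamped Langevin equation
#' `dx = -(D/kT) grad U(x) dt + sqrt(2 D dt) xi` with a fixed-step
#' Euler--Maruyama scheme. The time step is the frame spacing of `cfg`
#' (dimensionless time units equal to ns here). For a symmetric double well
#' run long enough the two well occupancies equalize; on a flat potential the
#' mean-squared displacement grows as `2 D t` per dimension.
#'
#' @param spec A [well_spec()].
#' @param cfg A [generator_config()]; one position is recorded per frame at
#'   the configured spacing.
#' @param x0 Optional starting point (defaults to the first well centre).
#' @param n_substeps Integration substeps per recorded frame. The default
#'   subdivides the frame spacing until the deterministic step is stable for
#'   the well stiffness (`D/kT * dt * U'' <= 0.1`).
#' @return Matrix `n_frames x d` of positions with attributes `spacing`
#'   (frame spacing) and `spec`.
#' @export
langevin_double_well <- function(spec, cfg, x0 = NULL, n_substeps = NULL) {
  stopifnot(inherits(spec, "well_spec"), inherits(cfg, "generator_config"))
  d <- ncol(spec$centers)
  if (is.null(x0)) x0 <- spec$centers[1L, ]
  stopifnot(length(x0) == d)
  n <- cfg$n_frames
  dt <- cfg$frame_spacing_ns
  D <- spec$diffusion_coeff
  kT <- spec$temperature_factor
  if (is.null(n_substeps)) {
    # curvature at the minima: 8h/s^2 for the quartic double well, h for the
    # harmonic single well (plus the kT transverse confinement)
    stiff <- if (nrow(spec$centers) == 2L) {
      s <- sqrt(sum((spec$centers[2L, ] - spec$centers[1L, ])^2)) / 2
      max(8 * spec$barrier_height / s^2, kT)
    } else max(spec$barrier_height, 0)
    n_substeps <- max(1L, ceiling(dt * D / kT * stiff / 0.1))
  }
  n_substeps <- as.integer(n_substeps)
  dt_sub <- dt / n_substeps
  noise_sd <- sqrt(2 * D * dt_sub)
  mob <- D / kT * dt_sub
  xi <- with_seed(cfg$seed, matrix(rnorm(n * n_substeps * d),
                                   n * n_substeps, d))
  out <- matrix(NA_real_, n, d)
  x <- matrix(x0, 1L, d)
  k <- 0L
  for (t in seq_len(n)) {
    for (s in seq_len(n_substeps)) {
      k <- k + 1L
      g <- well_gradient(spec, x)
      x <- x - mob * g + noise_sd * xi[k, , drop = FALSE]
    }
    out[t, ] <- x
  }
  attr(out, "spacing") <- dt
  attr(out, "spec") <- spec
  out
}

#' Gaussian positional ensemble with prescribed cross-correlations
#'
#' Generates trajectory frames as `reference + displacement`, where per-site
#' displacements are isotropic Gaussians with standard deviation `site_sd[i]`
#' per Cartesian axis and prescribed site-site correlation: for each axis the
#' site displacement vector is drawn from `N(0, diag(sd) C diag(sd))` via the
#' symmetric matrix square root, and the three axes are independent. The
#' resulting dynamical cross-correlation matrix of the ensemble converges to
#' `correlation` entrywise, and the per-site RMSF to `site_sd * sqrt(3)`.
#'
#' @param reference Reference coordinates, matrix `n_sites x 3` (Angstrom),
#'   or a `trajectory` whose first frame is used (its topology is kept).
#' @param site_sd Per-site positive standard deviations (Angstrom per axis);
#'   recycled if scalar.
#' @param correlation Symmetric positive-semidefinite site correlation matrix
#'   with unit diagonal. A non-PSD matrix is an error; no nearest-PSD repair
#'   is applied.
#' @param cfg A [generator_config()].
#' @return A [trajectory()] with `cfg$n_frames` frames.
#' @export
gaussian_ensemble <- function(reference, site_sd, correlation = NULL, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  topo <- NULL
  if (inherits(reference, "trajectory")) {
    topo <- reference$topology
    reference <- reference$coords[1L, , ]
  }
  reference <- as.matrix(reference)
  stopifnot(ncol(reference) == 3L)
  ns <- nrow(reference)
  site_sd <- rep_len(as.numeric(site_sd), ns)
  if (any(site_sd < 0)) stop("site_sd must be non-negative", call. = FALSE)
  if (is.null(correlation)) correlation <- diag(ns)
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation), tolerance = 1e-10))) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (max(abs(diag(correlation) - 1)) > 1e-10) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(correlation, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop(paste("correlation matrix is not positive semidefinite",
               "(no nearest-PSD repair is applied; fix the input)"),
         call. = FALSE)
  }
  vals <- pmax(ev$values, 0)
  # symmetric square root of diag(sd) C diag(sd)
  sqC <- ev$vectors %*% (sqrt(vals) * t(ev$vectors))
  L <- diag(site_sd, ns) %*% sqC
  n <- cfg$n_frames
  disp <- with_seed(cfg$seed, {
    lapply(1:3, function(ax) matrix(rnorm(n * ns), n, ns) %*% t(L))
  })
  coords <- array(NA_real_, c(n, ns, 3L))
  for (ax in 1:3) {
    coords[, , ax] <- sweep(disp[[ax]], 2L, reference[, ax], `+`)
  }
  if (is.null(topo)) topo <- pseudo_ca_topology(ns)
  trajectory(topo, coords, frame_spacing_ns = cfg$frame_spacing_ns)
}

# canonical MM/PBSA component keys (ASCII)
energy_component_keys <- c("dE_vdw", "dE_ele", "dG_solv", "dE_int", "dG_pb", "dG_np")

#' Synthetic per-frame MM/PBSA component table
#'
#' Draws independent Gaussian per-frame values for each named energy
#' component (kcal/mol). Component names use the ASCII aliases
#' `dE_vdw`, `dE_ele`, `dG_solv`, and optionally `dE_int`, `dG_pb`, `dG_np`.
#'
#' @param component_means Named numeric vector of component means.
#' @param component_sds Named numeric vector of component standard deviations
#'   (same names, all >= 0).
#' @param cfg A [generator_config()].
#' @return An [energy_table()] with `cfg$n_frames` rows.
#' @export
synth_energy_table <- function(component_means, component_sds, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  keys <- names(component_means)
  if (is.null(keys) || !setequal(keys, names(component_sds))) {
    stop("component_means and component_sds must share the same names",
         call. = FALSE)
  }
  unknown <- setdiff(keys, energy_component_keys)
  if (length(unknown)) {
    stop(sprintf("unknown energy component(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(energy_component_keys, collapse = ", ")),
         call. = FALSE)
  }
  if (any(component_sds < 0)) stop("component sds must be >= 0", call. = FALSE)
  n <- cfg$n_frames
  cols <- with_seed(cfg$seed, {
    lapply(keys, function(k) rnorm(n, component_means[[k]], component_sds[[k]]))
  })
  names(cols) <- keys
  energy_table(as.data.frame(cols, check.names = FALSE))
}
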