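# Structural observables. Superposition is Kabsch (SVD) on the selected
# atoms — the cpptraj-equivalent default for best-fit RMSD.

#' Kabsch superposition
#'
#' Finds the proper rotation `R` (det = +1) and translation minimizing the
#' weighted RMSD between `mobile` and `reference`. The fitted coordinates are
#' `mobile %*% R + translation` (row-vector convention).
#'
#' @param mobile,reference Matrices `n x 3` with the same `n >= 3`.
#' @param weights Optional non-negative per-point weights.
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom) and `fitted` (transformed mobile coordinates).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    stop("mobile and reference must have the same number of points", call. = FALSE)
  }
  n <- nrow(mobile)
  stopifnot(n >= 3L, ncol(mobile) == 3L)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(reference, 2L, cr)
  H <- t(X * w) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  fitted <- sweep(fitted, 2L, cr, `+`)
  list(rotation = R, translation = cr - drop(cm %*% R), rmsd = rmsd,
       fitted = fitted)
}

# plain (no-superposition) RMSD between two coordinate sets
raw_rmsd <- function(a, b, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(a))
  w <- weights / sum(weights)
  sqrt(sum(w * rowSums((a - b)^2)))
}

#' Per-frame best-fit RMSD series
#'
#' Superposes each frame onto the reference using `fit_selection` and reports
#' the RMSD over `selection`. Separate fit and measurement selections support
#' ligand-style RMSD with the binding site aligned.
#'
#' @param traj A [trajectory()].
#' @param reference Frame index into `traj` (default 1) or an `n_atoms x 3`
#'   coordinate matrix.
#' @param selection Atom indices measured (default: all C-alpha atoms, or all
#'   atoms if none are named CA).
#' @param fit_selection Atom indices used for the superposition (default:
#'   `selection`).
#' @param superpose Set `FALSE` to skip fitting and measure raw displacement.
#' @return Object of class `observable_series`: data frame with columns
#'   `frame`, `time_ns`, `value` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL,
                        fit_selection = selection, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  selection <- default_selection(traj, selection)
  if (length(selection) == 0L) stop("empty selection", call. = FALSE)
  if (is.null(fit_selection)) fit_selection <- selection
  ref <- if (is.matrix(reference)) reference else traj$coords[reference, , ]
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(f) {
    fr <- traj$coords[f, , ]
    if (superpose) {
      fit <- kabsch_superpose(fr[fit_selection, , drop = FALSE],
                              ref[fit_selection, , drop = FALSE])
      moved <- sweep(fr %*% fit$rotation, 2L, fit$translation, `+`)
      raw_rmsd(moved[selection, , drop = FALSE],
               ref[selection, , drop = FALSE])
    } else {
      raw_rmsd(fr[selection, , drop = FALSE], ref[selection, , drop = FALSE])
    }
  }, numeric(1L))
  observable_series("rmsd", vals, traj$frame_spacing_ns, "Angstrom")
}

observable_series <- function(name, values, spacing, units) {
  df <- data.frame(frame = seq_along(values),
                   time_ns = (seq_along(values) - 1L) * spacing,
                   value = values)
  attr(df, "observable") <- name
  attr(df, "units") <- units
  class(df) <- c("observable_series", "data.frame")
  df
}

default_selection <- function(traj, selection) {
  if (!is.null(selection)) return(selection)
  ca <- select_atoms(traj$topology, name = "CA")
  if (length(ca)) ca else seq_len(nrow(traj$topology))
}

# standard atomic masses for mass-weighted observables
element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, SE = 78.971, FE = 55.845,
                    ZN = 65.38, MG = 24.305, CA = 40.078, NA. = 22.99,
                    K = 39.098, CL = 35.45, F = 18.998, BR = 79.904)

lookup_masses <- function(elements) {
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  m <- element_masses[key]
  if (any(is.na(m))) {
    stop(sprintf("no mass for element(s): %s",
                 paste(unique(elements[is.na(m)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(m)
}

#' Radius of gyration of one frame
#'
#' `Rg = sqrt( sum w_i |r_i - rbar|^2 / sum w_i )` with `rbar` the (weighted)
#' centroid. Invariant under rigid-body motion.
#'
#' @param frame `n x 3` coordinate matrix, or a [trajectory()] (then `which`
#'   picks the frame).
#' @param selection Optional atom indices.
#' @param mass_weighted Use atomic masses as weights (requires elements
#'   resolvable from the topology or `masses`).
#' @param masses Optional explicit weights.
#' @param which Frame index when `frame` is a trajectory.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, mass_weighted = FALSE,
                               masses = NULL, which = 1L) {
  topo <- NULL
  if (inherits(frame, "trajectory")) {
    topo <- frame$topology
    frame <- frame$coords[which, , ]
  }
  frame <- as.matrix(frame)
  if (!is.null(selection)) {
    frame <- frame[selection, , drop = FALSE]
    if (!is.null(topo)) topo <- topo[selection, , drop = FALSE]
  }
  if (nrow(frame) == 0L) stop("empty selection", call. = FALSE)
  w <- if (!is.null(masses)) masses
  else if (mass_weighted) {
    if (is.null(topo)) stop("mass weighting needs a topology or masses",
                            call. = FALSE)
    lookup_masses(topo$element)
  } else rep(1, nrow(frame))
  w <- w / sum(w)
  ctr <- colSums(frame * w)
  sqrt(sum(w * rowSums(sweep(frame, 2L, ctr)^2)))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams rmsd_series
#' @param mass_weighted,masses See [radius_of_gyration()].
#' @return An `observable_series` (Angstrom).
#' @export
rg_series <- function(traj, selection = NULL, mass_weighted = FALSE,
                      masses = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    radius_of_gyration(traj$coords[f, , ], selection, mass_weighted, masses),
    numeric(1L))
  observable_series("rg", vals, traj$frame_spacing_ns, "Angstrom")
}

# Superpose all frames of a coordinate block onto a reference; returns the
# block. coords: frames x atoms x 3.
superpose_block <- function(coords, ref, fit_idx) {
  nf <- dim(coords)[1L]
  for (f in seq_len(nf)) {
    fr <- coords[f, , ]
    fit <- kabsch_superpose(fr[fit_idx, , drop = FALSE],
                            ref[fit_idx, , drop = FALSE])
    coords[f, , ] <- sweep(fr %*% fit$rotation, 2L, fit$translation, `+`)
  }
  coords
}

# Iteratively superpose frames to their mean structure (used by RMSF);
# converges in a few passes.
superpose_to_mean <- function(coords, fit_idx, max_iter = 10L, tol = 1e-6) {
  ref <- apply(coords, c(2L, 3L), mean)
  for (i in seq_len(max_iter)) {
    coords <- superpose_block(coords, ref, fit_idx)
    new_ref <- apply(coords, c(2L, 3L), mean)
    shift <- sqrt(max(rowSums((new_ref - ref)^2)))
    ref <- new_ref
    if (shift < tol) break
  }
  list(coords = coords, mean = ref)
}

#' Root-mean-square fluctuation per site
#'
#' `RMSF_i = sqrt( < |r_i(t) - <r_i>|^2 > )` over frames, optionally after
#' iterative superposition of all frames onto the evolving mean structure.
#' For an isotropic Gaussian ensemble with per-axis standard deviation
#' `sigma_i`, `RMSF_i -> sigma_i * sqrt(3)`.
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection Atom indices (default C-alpha).
#' @param superpose Superpose frames onto the mean structure first.
#' @return Data frame with columns `site` (atom index), `resno`, `rmsf`
#'   (Angstrom).
#' @export
rmsf <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames", call. = FALSE)
  selection <- default_selection(traj, selection)
  coords <- traj$coords[, selection, , drop = FALSE]
  if (superpose) {
    coords <- superpose_to_mean(coords, seq_along(selection))$coords
  }
  mu <- apply(coords, c(2L, 3L), mean)
  dev2 <- 0
  for (ax in 1:3) dev2 <- dev2 + sweep(coords[, , ax], 2L, mu[, ax])^2
  data.frame(site = selection, resno = traj$topology$resno[selection],
             rmsf = sqrt(colMeans(dev2)))
}

#' Dynamical cross-correlation matrix
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` where `dr` is the
#' deviation from the time-mean position after one superposition pass onto
#' the mean structure. Entries lie in \[-1, 1\]; +1 is fully correlated, -1
#' anti-correlated motion. Sites with zero positional variance give `NaN`
#' rows/columns with a warning (absence of motion is not absence of
#' correlation).
#'
#' @param traj A [trajectory()] with >= 2 frames.
#' @param selection Atom indices (default C-alpha).
#' @param superpose Superpose frames before analysis.
#' @return Symmetric matrix of class `dccm_matrix` with unit diagonal.
#' @export
dccm <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("DCCM needs at least 2 frames", call. = FALSE)
  selection <- default_selection(traj, selection)
  coords <- traj$coords[, selection, , drop = FALSE]
  if (superpose) {
    # single pass: fit all frames to the raw mean, then recentre on the
    # post-fit mean (standard DCCM practice; no iteration)
    ref <- apply(coords, c(2L, 3L), mean)
    coords <- superpose_block(coords, ref, seq_along(selection))
  }
  mu <- apply(coords, c(2L, 3L), mean)
  ns <- length(selection)
  cmat <- matrix(0, ns, ns)
  dx <- sweep(coords[, , 1L], 2L, mu[, 1L])
  dy <- sweep(coords[, , 2L], 2L, mu[, 2L])
  dz <- sweep(coords[, , 3L], 2L, mu[, 3L])
  cmat <- (t(dx) %*% dx + t(dy) %*% dy + t(dz) %*% dz) / nrow(dx)
  v <- diag(cmat)
  if (any(v <= 0)) {
    warning("site(s) with zero positional variance: DCCM entries set to NaN")
    v[v <= 0] <- NA_real_
  }
  norm <- sqrt(outer(v, v))
  out <- cmat / norm
  out[is.na(norm)] <- NaN
  diag(out)[!is.na(v)] <- 1
  out <- pmin(pmax(out, -1), 1)
  attr(out, "selection") <- selection
  class(out) <- c("dccm_matrix", class(out))
  out
}

#' Inter-group pocket distance series
#'
#' Per-frame Euclidean distance between the C-alpha centroids of two residue
#' groups. The defaults are the helix-1 (residues 12-18) and helix-7
#' (residues 109-119) windows bracketing a luciferase-like catalytic pocket.
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Residue-number vectors.
#' @return An `observable_series` (Angstrom).
#' @export
pocket_distance <- function(traj, group_a = 12:18, group_b = 109:119) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- select_atoms(traj$topology, name = "CA", resno = group_a)
  ib <- select_atoms(traj$topology, name = "CA", resno = group_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("residue range resolves to no C-alpha atoms", call. = FALSE)
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    ca <- colMeans(matrix(traj$coords[f, ia, ], length(ia), 3L))
    cb <- colMeans(matrix(traj$coords[f, ib, ], length(ib), 3L))
    sqrt(sum((ca - cb)^2))
  }, numeric(1L))
  observable_series("pocket_distance", vals, traj$frame_spacing_ns, "Angstrom")
}
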