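# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral sphere quadrature.

# Bondi van der Waals radii (Angstrom)
bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 P = 1.80, S = 1.80, CL = 1.75, BR = 1.85, I = 1.98,
                 SE = 1.90, ZN = 1.39, MG = 1.73, NA. = 2.27, K = 2.75,
                 CA = 2.31, FE = 2.00)

lookup_radii <- function(elements, radii = NULL) {
  tab <- bondi_radii
  if (!is.null(radii)) {
    nm <- toupper(names(radii))
    nm[nm == "NA"] <- "NA."
    tab[nm] <- radii
  }
  key <- toupper(elements)
  key[key == "NA"] <- "NA."
  r <- tab[key]
  if (any(is.na(r))) {
    stop(sprintf("no van der Waals radius for element(s): %s (supply `radii`)",
                 paste(unique(elements[is.na(r)]), collapse = ", ")),
         call. = FALSE)
  }
  unname(r)
}

# deterministic, near-uniform unit-sphere points (golden-spiral lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atomic van der Waals surface: each atom's
#' expanded sphere (radius `r_vdw + probe_radius`) is sampled with a
#' deterministic golden-spiral lattice of `n_sphere_points` test points, and
#' the accessible fraction is the fraction not buried inside any neighbour's
#' expanded sphere. The estimate improves monotonically (in quadrature error)
#' with `n_sphere_points`. An isolated atom of radius r gives
#' `4 pi (r + probe)^2` within quadrature error.
#'
#' @param frame `n x 3` coordinate matrix, or a [trajectory()] (then `which`
#'   selects the frame and elements come from the topology).
#' @param elements Element symbols per atom (needed when `frame` is a bare
#'   matrix).
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points Quadrature points per atom.
#' @param radii Named vector overriding/extending the Bondi radius table.
#' @param which Frame index when `frame` is a trajectory.
#' @return List with `total` (Angstrom^2) and `per_atom` vector.
#' @export
sasa <- function(frame, elements = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L, radii = NULL, which = 1L) {
  if (inherits(frame, "trajectory")) {
    elements <- frame$topology$element
    frame <- frame$coords[which, , ]
  }
  frame <- as.matrix(frame)
  n <- nrow(frame)
  if (is.null(elements)) stop("element symbols are required", call. = FALSE)
  stopifnot(length(elements) == n, probe_radius >= 0, n_sphere_points >= 4)
  r <- lookup_radii(elements, radii) + probe_radius
  pts <- sphere_points(as.integer(n_sphere_points))
  d2 <- as.matrix(dist(frame))^2
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    neigh <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2L, frame[i, ], `+`)
    acc <- rep(TRUE, nrow(surf))
    for (j in neigh) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(surf[acc, , drop = FALSE], 2L, frame[j, ])^2)
      acc[acc] <- dj2 > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Per-frame total SASA series
#'
#' @param traj A [trajectory()].
#' @inheritParams sasa
#' @return An `observable_series` (Angstrom^2).
#' @export
sasa_series <- function(traj, probe_radius = 1.4, n_sphere_points = 240L,
                        radii = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    sasa(traj$coords[f, , ], traj$topology$element, probe_radius,
         n_sphere_points, radii)$total, numeric(1L))
  observable_series("sasa", vals, traj$frame_spacing_ns, "Angstrom^2")
}
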