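# Geometry helpers shared by observable tests: an internal-coordinate (NeRF)
# backbone builder so ideal helix / strand trajectories can be generated with
# known secondary structure.

# place atom D given A-B-C with bond |CD|, angle B-C-D (deg), dihedral
# A-B-C-D (deg)
place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- -dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Poly-alanine backbone (N, CA, C, O per residue) with uniform phi/psi.
# Ideal alpha helix: phi = -57, psi = -47; extended strand: -135 / 135.
build_backbone <- function(n_res, phi, psi, omega = 180) {
  bl <- c(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231)
  ba <- c(n_ca_c = 111.2, ca_c_n = 116.2, c_n_ca = 121.7, ca_c_o = 120.5)
  coords <- matrix(NA_real_, n_res * 4L, 3L)
  rownames(coords) <- paste(rep(c("N", "CA", "C", "O"), n_res),
                            rep(seq_len(n_res), each = 4L))
  idx <- function(i, atom) (i - 1L) * 4L + match(atom, c("N", "CA", "C", "O"))
  coords[1L, ] <- c(0, 0, 0)
  coords[2L, ] <- c(bl["n_ca"], 0, 0)
  ang <- ba["n_ca_c"] * pi / 180
  coords[3L, ] <- coords[2L, ] + bl["ca_c"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    N <- coords[idx(i, "N"), ]; CA <- coords[idx(i, "CA"), ]
    C <- coords[idx(i, "C"), ]
    # carbonyl O anti to the next amide N: dihedral N-CA-C-O = psi + 180
    coords[idx(i, "O"), ] <- place_atom(N, CA, C, bl["c_o"], ba["ca_c_o"],
                                        psi + 180)
    if (i < n_res) {
      Nn <- place_atom(N, CA, C, bl["c_n"], ba["ca_c_n"], psi)
      coords[idx(i + 1L, "N"), ] <- Nn
      CAn <- place_atom(CA, C, Nn, bl["n_ca"], ba["c_n_ca"], omega)
      coords[idx(i + 1L, "CA"), ] <- CAn
      coords[idx(i + 1L, "C"), ] <- place_atom(C, Nn, CAn, bl["ca_c"],
                                               ba["n_ca_c"], phi)
    }
  }
  coords
}

backbone_trajectory <- function(frames_list, spacing = 0.1) {
  n_res <- nrow(frames_list[[1L]]) / 4L
  topo <- topology(name = rep(c("N", "CA", "C", "O"), n_res),
                   element = rep(c("N", "C", "C", "O"), n_res),
                   resno = rep(seq_len(n_res), each = 4L),
                   resname = "ALA")
  coords <- array(NA_real_, c(length(frames_list), n_res * 4L, 3L))
  for (f in seq_along(frames_list)) coords[f, , ] <- frames_list[[f]]
  trajectory(topo, coords, spacing)
}

# independent quaternion (Horn) superposition oracle for Kabsch tests
horn_rmsd <- function(mobile, reference) {
  X <- scale(mobile, scale = FALSE)
  Y <- scale(reference, scale = FALSE)
  Sxx <- t(X) %*% Y
  S <- Sxx
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X^2) + sum(Y^2) - 2 * lam) / nrow(X)
  sqrt(max(msd, 0))
}

# random row-stochastic reversible transition matrix from symmetric counts
random_reversible_T <- function(n, seed) {
  C <- with_seed_test(seed, matrix(runif(n * n, 0.1, 5), n, n))
  C <- C + t(C)
  T <- C / rowSums(C)
  list(T = T, stationary = rowSums(C) / sum(C))
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# wrap a plain transition matrix as a markov_model for TPT tests
as_markov_model <- function(T, stationary = NULL, reversible = TRUE) {
  if (is.null(stationary)) {
    e <- eigen(t(T))
    v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
    stationary <- v / sum(v)
  }
  structure(list(T = T, counts = T, active_set = seq_len(nrow(T)),
                 stationary = stationary,
                 eigenvalues = eigen(T, only.values = TRUE)$values,
                 lag_steps = 1L, lag_ns = NA_real_, reversible = reversible),
            class = "markov_model")
}
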