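# Alpha-helix content via a Kabsch-Sander reduction: backbone i -> i+4
# hydrogen bonds from the electrostatic model
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,
# bond when E < -0.5 kcal/mol. Only the alpha-helix class is assigned (no
# sheets/turns): residues i+1..i+4 are helical when 4-turns exist at both
# i-1 and i (the minimal-helix rule). Amide hydrogens are reconstructed
# geometrically from the preceding carbonyl: H = N + unit(C_prev - O_prev).

hbond_energy <- function(N, H, C, O) {
  r <- function(a, b) sqrt(sum((a - b)^2))
  q1q2f <- 0.084 * 332
  q1q2f * (1 / r(O, N) + 1 / r(C, H) - 1 / r(O, H) - 1 / r(C, N))
}

# Extract per-residue backbone atom indices (N, CA, C, O) in residue order.
backbone_index <- function(topo, residue_range = NULL) {
  keep <- if (is.null(residue_range)) unique(topo$resno) else residue_range
  res <- keep[keep %in% topo$resno]
  idx <- lapply(res, function(rn) {
    sel <- which(topo$resno == rn)
    find <- function(nm) {
      i <- sel[topo$name[sel] == nm]
      if (length(i)) i[1L] else NA_integer_
    }
    c(N = find("N"), CA = find("CA"), C = find("C"), O = find("O"))
  })
  m <- do.call(rbind, idx)
  ok <- !apply(is.na(m), 1L, any)
  if (any(!ok)) {
    warning(sprintf("residue(s) %s lack backbone atoms and are excluded",
                    paste(res[!ok], collapse = ", ")))
  }
  list(resno = res[ok], idx = m[ok, , drop = FALSE])
}

# per-frame helix flags for the residues in `bb`
frame_helix_flags <- function(xyz, bb, energy_cutoff = -0.5) {
  nres <- length(bb$resno)
  # reconstructed H for residues 2..nres (needs previous C=O)
  Hpos <- matrix(NA_real_, nres, 3L)
  for (i in 2:nres) {
    if (bb$resno[i] - bb$resno[i - 1L] != 1L) next  # chain break
    Cp <- xyz[bb$idx[i - 1L, "C"], ]
    Op <- xyz[bb$idx[i - 1L, "O"], ]
    Ni <- xyz[bb$idx[i, "N"], ]
    v <- Cp - Op
    Hpos[i, ] <- Ni + v / sqrt(sum(v^2))
  }
  turn <- rep(FALSE, nres)          # turn[i]: CO(i) -- HN(i+4) bond
  for (i in seq_len(nres - 4L)) {
    a <- i + 4L
    if (any(is.na(Hpos[a, ]))) next
    # only consecutive numbering qualifies as an i -> i+4 contact
    if (bb$resno[a] - bb$resno[i] != 4L) next
    E <- hbond_energy(N = xyz[bb$idx[a, "N"], ], H = Hpos[a, ],
                      C = xyz[bb$idx[i, "C"], ], O = xyz[bb$idx[i, "O"], ])
    turn[i] <- E < energy_cutoff
  }
  helix <- rep(FALSE, nres)
  if (nres >= 6L) {
    for (i in 2:(nres - 4L)) {
      if (turn[i - 1L] && turn[i]) helix[(i + 1L):(i + 4L)] <- TRUE
    }
  }
  helix
}

#' Alpha-helix content of a trajectory
#'
#' Assigns each residue in each frame as helical or not using the
#' Kabsch-Sander i -> i+4 hydrogen-bond energy criterion (bond when
#' E < -0.5 kcal/mol; minimal-helix rule of two consecutive 4-turns) and
#' reports the per-residue helix probability (fraction of frames helical)
#' and the per-frame helix fraction over the analysed range. Amide hydrogens
#' are reconstructed from the preceding carbonyl geometry, so backbone
#' N, CA, C, O atoms must be present; residues missing any are excluded with
#' a warning.
#'
#' @param traj A [trajectory()] whose topology includes backbone atoms.
#' @param residue_range Optional residue numbers to analyse (default: all).
#' @param energy_cutoff Hydrogen-bond energy threshold (kcal/mol).
#' @return List with `per_residue` (data frame: resno, helix_probability) and
#'   `per_frame` (data frame: frame, helix_fraction).
#' @export
helix_content <- function(traj, residue_range = NULL, energy_cutoff = -0.5) {
  stopifnot(inherits(traj, "trajectory"))
  bb <- backbone_index(traj$topology, residue_range)
  if (length(bb$resno) < 5L) {
    stop("need at least 5 consecutive residues with full backbones", call. = FALSE)
  }
  nf <- n_frames(traj)
  flags <- matrix(FALSE, nf, length(bb$resno))
  for (f in seq_len(nf)) {
    xyz <- matrix(traj$coords[f, , ], dim(traj$coords)[2L], 3L)
    flags[f, ] <- frame_helix_flags(xyz, bb, energy_cutoff)
  }
  list(per_residue = data.frame(resno = bb$resno,
                                helix_probability = colMeans(flags)),
       per_frame = data.frame(frame = seq_len(nf),
                              helix_fraction = rowMeans(flags)))
}
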