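# Structure / trajectory containers and I/O. Units are Angstrom, ns and
# kcal/mol throughout the package; no implicit conversion anywhere.

#' Atom topology
#'
#' Ordered per-atom metadata shared by all frames of a trajectory. Residue
#' identity is the triple (chain, residue number, insertion code), taken
#' verbatim from the input file; residues are never renumbered.
#'
#' @param name Atom names (e.g. `"CA"`).
#' @param element Element symbols (e.g. `"C"`).
#' @param resno Integer residue numbers.
#' @param resname Residue names (e.g. `"ALA"`).
#' @param chain Chain identifiers.
#' @param insert Insertion codes (`NA` when absent).
#' @return A data frame of class `topology`.
#' @export
topology <- function(name, element, resno, resname = "UNK", chain = "A",
                     insert = NA_character_) {
  n <- length(name)
  df <- data.frame(name = as.character(name),
                   element = as.character(element),
                   resno = as.integer(resno),
                   resname = rep_len(as.character(resname), n),
                   chain = rep_len(as.character(chain), n),
                   insert = rep_len(as.character(insert), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("topology", "data.frame")
  df
}

# N pseudo C-alpha sites on one chain, used when a generator has no topology.
pseudo_ca_topology <- function(n_sites) {
  topology(name = rep("CA", n_sites), element = rep("C", n_sites),
           resno = seq_len(n_sites), resname = "GLY")
}

#' Look up the C-alpha atom index of a residue
#'
#' @param topo A [topology()].
#' @param resno Residue number.
#' @param chain Optional chain filter.
#' @param insert Optional insertion-code filter (`NA` matches atoms without
#'   one).
#' @return Integer atom index. Errors if the residue has no C-alpha.
#' @export
calpha_index <- function(topo, resno, chain = NULL, insert = NA) {
  sel <- topo$name == "CA" & topo$resno == resno
  if (!is.null(chain)) sel <- sel & topo$chain == chain
  if (!is.null(insert)) {
    sel <- sel & if (is.na(insert)) is.na(topo$insert) else
      (!is.na(topo$insert) & topo$insert == insert)
  }
  idx <- which(sel)
  if (length(idx) == 0L) {
    stop(sprintf("no C-alpha atom for residue %s%s", resno,
                 if (is.null(chain)) "" else paste0(" chain ", chain)),
         call. = FALSE)
  }
  idx[1L]
}

#' Select atom indices from a topology
#'
#' @param topo A [topology()].
#' @param name Optional atom-name filter (e.g. `"CA"`).
#' @param resno Optional residue numbers to keep.
#' @param chain Optional chain filter.
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(topo, name = NULL, resno = NULL, chain = NULL) {
  sel <- rep(TRUE, nrow(topo))
  if (!is.null(name)) sel <- sel & topo$name %in% name
  if (!is.null(resno)) sel <- sel & topo$resno %in% resno
  if (!is.null(chain)) sel <- sel & topo$chain %in% chain
  which(sel)
}

#' Trajectory container
#'
#' Ordered coordinate frames over a fixed topology.
#'
#' @param topology A [topology()].
#' @param coords Array `n_frames x n_atoms x 3` (Angstrom). A single
#'   `n_atoms x 3` matrix is promoted to one frame.
#' @param frame_spacing_ns Frame spacing in ns.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, frame_spacing_ns = 0.1) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3L] == 3L)
  if (dim(coords)[2L] != nrow(topology)) {
    stop("coordinate frames and topology disagree on atom count", call. = FALSE)
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 frame_spacing_ns = as.numeric(frame_spacing_ns)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, %.4g ns/frame\n",
              dim(x$coords)[1L], dim(x$coords)[2L], x$frame_spacing_ns))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1L]

# Pre-validate the fixed coordinate columns of a PDB file so malformed
# records are reported with their line number (bio3d would silently coerce).
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  atom <- grep("^(ATOM  |HETATM)", rec)
  for (i in atom) {
    for (cols in list(c(31L, 38L), c(39L, 46L), c(47L, 54L))) {
      field <- substr(lines[i], cols[1L], cols[2L])
      if (is.na(suppressWarnings(as.numeric(field)))) {
        stop(sprintf("malformed coordinate field '%s' on line %d of %s",
                     trimws(field), i, path), call. = FALSE)
      }
    }
  }
  invisible(lines)
}

#' Read a PDB structure or multi-model trajectory
#'
#' Parses fixed-column ATOM/HETATM records (via bio3d). For alternate
#' locations only the highest-occupancy altloc of each atom is kept;
#' insertion codes are preserved in the residue identity. Multiple MODEL
#' blocks become trajectory frames.
#'
#' @param path Path to a PDB file.
#' @param frame_spacing_ns Frame spacing to attach (ns).
#' @return A [trajectory()] (one frame for a plain structure file).
#' @export
read_structure <- function(path, frame_spacing_ns = 0.1) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  keep <- seq_len(nrow(at))
  if (any(!is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    keep <- sort(ord[!duplicated(key[ord])])
  }
  at <- at[keep, , drop = FALSE]
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  xyz <- xyz[, cols, drop = FALSE]
  elem <- at$elesy
  if (any(is.na(elem) | elem == "")) {
    guess <- toupper(substr(gsub("^[0-9]+", "", at$elety), 1L, 1L))
    elem <- ifelse(is.na(elem) | elem == "", guess, elem)
  }
  topo <- topology(name = at$elety, element = elem, resno = at$resno,
                   resname = at$resid, chain = at$chain, insert = at$insert)
  nf <- nrow(xyz)
  na <- nrow(at)
  coords <- array(NA_real_, c(nf, na, 3L))
  for (ax in 1:3) coords[, , ax] <- xyz[, seq(ax, 3L * na, by = 3L), drop = FALSE]
  trajectory(topo, coords, frame_spacing_ns)
}

#' Write a trajectory to disk
#'
#' Supported formats: `"pdb"` (multi-model, fixed columns, 3-decimal
#' coordinates), `"xyz"` (xmol), and `"csv-array"` (a one-line JSON header
#' with shape/spacing followed by one CSV row per frame, full precision).
#'
#' @param traj A [trajectory()] with at least one frame.
#' @param path Output path.
#' @param format One of `"pdb"`, `"xyz"`, `"csv-array"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz", "csv-array")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectories are unwritable", call. = FALSE)
  topo <- traj$topology
  na <- nrow(topo)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      ins <- ifelse(is.na(topo$insert), " ", topo$insert)
      ch <- ifelse(is.na(topo$chain), " ", topo$chain)
      nm <- ifelse(nchar(topo$name) < 4L, sprintf(" %-3s", topo$name),
                   topo$name)
      lines <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(na) %% 100000L, nm, substr(topo$resname, 1L, 3L), ch,
        topo$resno %% 10000L, ins,
        traj$coords[f, , 1L], traj$coords[f, , 2L], traj$coords[f, , 3L],
        1, 0, topo$element)
      writeLines(lines, con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else if (format == "xyz") {
    for (f in seq_len(nf)) {
      writeLines(as.character(na), con)
      writeLines(sprintf("frame %d t= %.6f ns", f,
                         (f - 1L) * traj$frame_spacing_ns), con)
      writeLines(sprintf("%-2s %14.6f %14.6f %14.6f", topo$element,
                         traj$coords[f, , 1L], traj$coords[f, , 2L],
                         traj$coords[f, , 3L]), con)
    }
  } else {
    hdr <- jsonlite::toJSON(list(n_frames = nf, n_atoms = na,
                                 frame_spacing_ns = traj$frame_spacing_ns),
                            auto_unbox = TRUE, digits = NA)
    writeLines(paste0("#", hdr), con)
    flat <- matrix(aperm(traj$coords, c(3L, 2L, 1L)), nrow = nf, byrow = TRUE)
    writeLines(apply(flat, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = ",")), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Input path.
#' @param format One of `"pdb"`, `"xyz"`, `"csv-array"`.
#' @param frame_spacing_ns Spacing override for formats that do not store it.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz", "csv-array"),
                            frame_spacing_ns = 0.1) {
  format <- match.arg(format)
  if (format == "pdb") return(read_structure(path, frame_spacing_ns))
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") {
    frames <- list()
    i <- 1L
    elem <- NULL
    while (i <= length(lines)) {
      na <- as.integer(lines[i])
      block <- lines[(i + 2L):(i + 1L + na)]
      toks <- do.call(rbind, strsplit(trimws(block), "\\s+"))
      elem <- toks[, 1L]
      frames[[length(frames) + 1L]] <-
        matrix(as.numeric(toks[, 2:4]), na, 3L)
      i <- i + 2L + na
    }
    nf <- length(frames)
    coords <- array(NA_real_, c(nf, nrow(frames[[1L]]), 3L))
    for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
    topo <- pseudo_ca_topology(nrow(frames[[1L]]))
    topo$element <- elem
    return(trajectory(topo, coords, frame_spacing_ns))
  }
  hdr <- jsonlite::fromJSON(sub("^#", "", lines[1L]))
  vals <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, ",")[[1L]]))
  flat <- do.call(rbind, vals)
  coords <- aperm(array(t(flat), c(3L, hdr$n_atoms, hdr$n_frames)), c(3L, 2L, 1L))
  trajectory(pseudo_ca_topology(hdr$n_atoms), coords, hdr$frame_spacing_ns)
}

#' Per-node position/velocity feature export
#'
#' Exports each atom (node) as a six-dimensional feature per frame: position
#' and finite-difference velocity in x, y and z, the layout consumed by
#' relational-inference models. Velocity at frame t is
#' `(x[t+1] - x[t]) / frame_spacing_ns`, so the last frame is dropped.
#'
#' @param traj A [trajectory()] with at least 2 frames.
#' @param file Optional path; when given, a long-format CSV
#'   (frame, node, x, y, z, vx, vy, vz) is written.
#' @return Array `n_nodes x (n_frames - 1) x 6` with feature dimnames
#'   `x, y, z, vx, vy, vz`.
#' @export
export_nri_features <- function(traj, file = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames for finite-difference velocities",
                    call. = FALSE)
  na <- dim(traj$coords)[2L]
  dt <- traj$frame_spacing_ns
  pos <- traj$coords[-nf, , , drop = FALSE]
  vel <- (traj$coords[-1L, , , drop = FALSE] - pos) / dt
  feat <- array(NA_real_, c(na, nf - 1L, 6L),
                dimnames = list(NULL, NULL, c("x", "y", "z", "vx", "vy", "vz")))
  for (ax in 1:3) {
    feat[, , ax] <- t(pos[, , ax])
    feat[, , ax + 3L] <- t(vel[, , ax])
  }
  if (!is.null(file)) {
    long <- expand.grid(node = seq_len(na), frame = seq_len(nf - 1L))
    m <- sapply(1:6, function(k) as.vector(feat[, , k]))
    colnames(m) <- c("x", "y", "z", "vx", "vy", "vz")
    write.csv(cbind(long[, c("frame", "node")], m), file, row.names = FALSE)
  }
  feat
}
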