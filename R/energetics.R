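# MM/PBSA energy-component aggregation. All energies in kcal/mol.
# Canonical column names are ASCII: dE_vdw, dE_ele, dE_int, dG_pb, dG_np,
# dG_solv; the Unicode spellings used in published tables are accepted as
# aliases on ingestion.

energy_aliases <- c(
  "∆E_vdW" = "dE_vdw", "∆E_vdw" = "dE_vdw", "dE_vdW" = "dE_vdw",
  "ΔE_vdW" = "dE_vdw", "DELTA E_vdw" = "dE_vdw", "VDWAALS" = "dE_vdw",
  "∆E_ele" = "dE_ele", "ΔE_ele" = "dE_ele", "EEL" = "dE_ele",
  "∆E_int" = "dE_int", "ΔE_int" = "dE_int",
  "∆G_pb" = "dG_pb", "ΔG_pb" = "dG_pb", "EPB" = "dG_pb",
  "∆G_np" = "dG_np", "ΔG_np" = "dG_np", "ENPOLAR" = "dG_np",
  "∆G_solv" = "dG_solv", "∆G_sol" = "dG_solv",
  "ΔG_solv" = "dG_solv", "ΔG_sol" = "dG_solv", "dG_sol" = "dG_solv")

#' Per-frame MM/PBSA energy-component table
#'
#' Validates and normalizes a table of per-frame component energies. The
#' van der Waals (`dE_vdw`) and electrostatic (`dE_ele`) terms are required;
#' solvation may arrive as a single `dG_solv` column or as polar + nonpolar
#' (`dG_pb`, `dG_np`), in which case `dG_solv = dG_pb + dG_np` is formed on
#' ingestion. An internal-energy column `dE_int` is accepted (it cancels in
#' single-trajectory analyses and defaults to absent).
#'
#' @param x Data frame, or path to a CSV with one row per frame.
#' @return Data frame of class `energy_table` with canonical column names.
#' @export
energy_table <- function(x) {
  if (is.character(x)) x <- read.csv(x, check.names = FALSE)
  x <- as.data.frame(x, check.names = FALSE)
  nm <- names(x)
  hit <- nm %in% names(energy_aliases)
  nm[hit] <- energy_aliases[nm[hit]]
  names(x) <- nm
  x <- x[, nm %in% energy_component_keys, drop = FALSE]
  for (req in c("dE_vdw", "dE_ele")) {
    if (!req %in% names(x)) {
      stop(sprintf("missing required energy component: %s", req), call. = FALSE)
    }
  }
  if (!"dG_solv" %in% names(x)) {
    if (all(c("dG_pb", "dG_np") %in% names(x))) {
      x$dG_solv <- x$dG_pb + x$dG_np
    } else {
      stop("missing required energy component: dG_solv (or dG_pb + dG_np)",
           call. = FALSE)
    }
  }
  if (!all(vapply(x, function(col) all(is.finite(col)), logical(1L)))) {
    stop("energy components must be finite", call. = FALSE)
  }
  if (nrow(x) < 1L) stop("energy table needs at least one frame", call. = FALSE)
  class(x) <- c("energy_table", "data.frame")
  x
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by `sqrt(n)`. With
#' a single observation the SEM is undefined and reported as `NA`.
#'
#' @param values Numeric vector.
#' @return Scalar SEM (`NA` for n = 1).
#' @export
sem <- function(values) {
  n <- length(values)
  if (n < 1L) stop("need at least one value", call. = FALSE)
  if (n == 1L) return(NA_real_)
  sd(values) / sqrt(n)
}

#' Aggregate an energy-component table into a summary
#'
#' Derived quantities are computed per frame and then summarized:
#' `dG_gas = dE_ele + dE_vdw (+ dE_int)` (the gas-phase molecular-mechanics
#' term), `dG_total = dG_gas + dG_solv` (the enthalpy, `dH`). Each component
#' and derived quantity is reported with its Average, Std. Dev. (sample) and
#' Std. Err. of Mean. Because the derived quantities are per-frame sums,
#' their averages satisfy the summation identities exactly. When an entropy
#' term `-T dS` is supplied, the binding free energy
#' `dG_bind = dH - T dS` is appended; the headline quantity otherwise is
#' `dG_total`.
#'
#' @param table An [energy_table()] (or anything it accepts).
#' @param entropy_term Optional scalar `-T dS` (kcal/mol).
#' @return Object of class `energy_summary`: data frame with rows per
#'   quantity and columns `average`, `sd`, `sem`.
#' @export
aggregate_energy <- function(table, entropy_term = NULL) {
  tab <- energy_table(table)
  n <- nrow(tab)
  q <- list(dE_vdw = tab$dE_vdw, dE_ele = tab$dE_ele)
  if ("dE_int" %in% names(tab)) q$dE_int <- tab$dE_int
  q$dG_gas <- tab$dE_ele + tab$dE_vdw +
    if ("dE_int" %in% names(tab)) tab$dE_int else 0
  if ("dG_pb" %in% names(tab)) q$dG_pb <- tab$dG_pb
  if ("dG_np" %in% names(tab)) q$dG_np <- tab$dG_np
  q$dG_solv <- tab$dG_solv
  q$dG_total <- q$dG_gas + tab$dG_solv
  out <- data.frame(
    quantity = names(q),
    average = vapply(q, mean, numeric(1L)),
    sd = vapply(q, function(v) if (length(v) > 1L) sd(v) else 0, numeric(1L)),
    sem = vapply(q, sem, numeric(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(entropy_term)) {
    out <- rbind(out,
                 data.frame(quantity = "minus_TdS", average = entropy_term,
                            sd = NA_real_, sem = NA_real_),
                 data.frame(quantity = "dG_bind",
                            average = out$average[out$quantity == "dG_total"] +
                              entropy_term,
                            sd = NA_real_, sem = NA_real_))
  }
  attr(out, "n_frames") <- n
  class(out) <- c("energy_summary", "data.frame")
  out
}

#' @export
print.energy_summary <- function(x, digits = 4, ...) {
  cat(sprintf("MM/PBSA summary over %d frame(s) (kcal/mol)\n",
              attr(x, "n_frames")))
  disp <- data.frame(
    `Energy Component` = x$quantity,
    Average = sprintf("%.*f", digits, x$average),
    `Std. Dev.` = sprintf("%.*f", digits, x$sd),
    `Std. Err. of Mean` = ifelse(is.na(x$sem), "-",
                                 sprintf("%.*f", digits, x$sem)),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Extract a summarized quantity
#'
#' @param summary An `energy_summary`.
#' @param quantity Row name, e.g. `"dG_gas"`, `"dG_total"`.
#' @param stat One of `"average"`, `"sd"`, `"sem"`.
#' @return Scalar value.
#' @export
energy_value <- function(summary, quantity, stat = "average") {
  stopifnot(inherits(summary, "energy_summary"))
  i <- match(quantity, summary$quantity)
  if (is.na(i)) stop(sprintf("no quantity '%s' in summary", quantity),
                     call. = FALSE)
  summary[[stat]][i]
}

#' Rank per-residue binding-energy contributions
#'
#' Sorts residues by contribution ascending (most favourable, i.e. most
#' negative, first); ties are broken by residue number.
#'
#' @param per_residue_table Data frame with columns `resno` and `energy`
#'   (kcal/mol).
#' @param top_n Optionally truncate to the strongest contributors.
#' @return The table sorted, with a `rank` column.
#' @export
rank_residue_contributions <- function(per_residue_table, top_n = NULL) {
  tab <- as.data.frame(per_residue_table)
  stopifnot(all(c("resno", "energy") %in% names(tab)), nrow(tab) >= 1L)
  tab <- tab[order(tab$energy, tab$resno), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  if (!is.null(top_n)) tab <- head(tab, top_n)
  tab
}
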