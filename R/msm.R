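# Microstate discretization and Markov state model estimation/validation.

# squared Euclidean distances between rows of x (n x d) and rows of c (k x d)
sq_dists <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  outer(xx, cc, `+`) - 2 * x %*% t(centers)
}

#' k-means clustering with k-means++ initialization
#'
#' Lloyd iterations from a k-means++ seeding, converging when the maximum
#' centre shift drops below `tol` (or `max_iter` is reached). Inertia (the
#' within-cluster sum of squared distances) is non-increasing over
#' iterations.
#'
#' @param samples Numeric matrix `n x d` (a vector is treated as 1-D).
#' @param k Number of clusters; must not exceed the number of distinct
#'   samples.
#' @param seed Integer RNG seed for the initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @param tol Convergence threshold on the centre shift.
#' @return Object of class `kmeans_result`: list with `centers` (`k x d`),
#'   `assignments` (1-based), `inertia`, `n_iter`.
#' @export
kmeans_cluster <- function(samples, k, seed = 1L, max_iter = 200L, tol = 1e-8) {
  x <- as.matrix(samples)
  storage.mode(x) <- "double"
  n <- nrow(x)
  k <- as.integer(k)
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    stop(sprintf("k = %d exceeds the number of distinct samples (%d)",
                 k, n_distinct), call. = FALSE)
  }
  centers <- with_seed(seed, {
    # k-means++: first centre uniform, then D^2-weighted
    ctr <- x[sample.int(n, 1L), , drop = FALSE]
    while (nrow(ctr) < k) {
      d2 <- apply(sq_dists(x, ctr), 1L, min)
      d2 <- pmax(d2, 0)
      if (sum(d2) == 0) {
        cand <- which(!duplicated(rbind(ctr, x))[-seq_len(nrow(ctr))])
        ctr <- rbind(ctr, x[cand[1L], ])
      } else {
        ctr <- rbind(ctr, x[sample.int(n, 1L, prob = d2), ])
      }
    }
    ctr
  })
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- sq_dists(x, centers)
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      members <- assign == j
      if (any(members)) {
        new_centers[j, ] <- colMeans(x[members, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the farthest sample
        far <- which.max(apply(d2, 1L, min))
        new_centers[j, ] <- x[far, ]
      }
    }
    shift <- sqrt(max(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) break
  }
  d2 <- sq_dists(x, centers)
  assign <- max.col(-d2, ties.method = "first")
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  structure(list(centers = centers, assignments = assign,
                 inertia = max(inertia, 0), n_iter = it),
            class = "kmeans_result")
}

#' Assign samples to the nearest cluster centre
#'
#' Ties are broken by the lowest centre index. Each resulting cluster is a
#' microstate of the discrete trajectory.
#'
#' @param samples Matrix `n x d` (vector treated as 1-D).
#' @param centers Matrix `k x d` of cluster centres.
#' @return Integer microstate labels (1-based), class `discrete_trajectory`.
#' @export
assign_microstates <- function(samples, centers) {
  x <- as.matrix(samples)
  centers <- as.matrix(centers)
  if (nrow(centers) == 0L) stop("centers must be non-empty", call. = FALSE)
  if (ncol(x) != ncol(centers)) {
    stop("samples and centers differ in dimensionality", call. = FALSE)
  }
  d2 <- sq_dists(x, centers)
  structure(max.col(-d2, ties.method = "first"),
            class = c("discrete_trajectory", "integer"))
}

#' Transition count matrix of a discrete trajectory
#'
#' @param dtraj Integer state labels (1-based).
#' @param lag_steps Lag in steps (>= 1, < length of `dtraj`).
#' @param mode `"sliding"` counts every pair `(t, t + lag)` (the default,
#'   maximizing data use); `"strided"` counts non-overlapping pairs at
#'   `t = 1, 1 + lag, ...`.
#' @param n_states Number of states (default: `max(dtraj)`).
#' @return Square count matrix.
#' @export
count_matrix <- function(dtraj, lag_steps, mode = c("sliding", "strided"),
                         n_states = NULL) {
  mode <- match.arg(mode)
  dtraj <- as.integer(dtraj)
  lag_steps <- as.integer(lag_steps)
  L <- length(dtraj)
  if (lag_steps < 1L) stop("lag_steps must be >= 1", call. = FALSE)
  if (lag_steps >= L) stop("lag must be smaller than the trajectory length",
                           call. = FALSE)
  if (is.null(n_states)) n_states <- max(dtraj)
  from_idx <- if (mode == "sliding") seq_len(L - lag_steps)
              else seq(1L, L - lag_steps, by = lag_steps)
  from <- dtraj[from_idx]
  to <- dtraj[from_idx + lag_steps]
  counts <- matrix(0, n_states, n_states)
  tab <- table(factor(from, levels = seq_len(n_states)),
               factor(to, levels = seq_len(n_states)))
  counts <- matrix(as.numeric(tab), n_states, n_states)
  counts
}

# left stationary eigenvector of a stochastic matrix
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# reversible maximum-likelihood transition matrix (detailed balance) by the
# standard fixed-point iteration on the symmetric flow variables x_ij
reversible_mle <- function(counts, tol = 1e-10, max_iter = 100000L) {
  csym <- counts + t(counts)
  ci <- rowSums(counts)
  x <- csym / sum(csym)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, `+`)
    xnew <- csym / denom
    xnew[csym == 0] <- 0
    xnew <- xnew / sum(xnew)
    delta <- max(abs(xnew - x))
    x <- xnew
    if (delta < tol) break
  }
  T <- x / rowSums(x)
  list(T = T, stationary = rowSums(x) / sum(x))
}

#' Estimate a Markov state model from transition counts
#'
#' Restricts the counts to the largest strongly-connected set of states
#' (ergodic trimming), then estimates the row-stochastic transition matrix:
#' plain row normalization (`reversible = FALSE`) or the detailed-balance
#' maximum-likelihood estimate by fixed-point iteration to `1e-10`
#' (`reversible = TRUE`). The stationary distribution is the leading left
#' eigenvector. Eigenvalues are sorted by real part (descending), ties broken
#' by the imaginary part.
#'
#' @param counts Square non-negative count matrix (or a `dtraj` via
#'   [count_matrix()] upstream).
#' @param reversible Enforce detailed balance.
#' @param prior_count Pseudo-count added to every observed (nonzero,
#'   symmetrized) transition.
#' @param lag_steps,lag_ns Lag bookkeeping attached to the model.
#' @return Object of class `markov_model`: list with `T`, `counts`,
#'   `active_set` (original state labels retained), `stationary`,
#'   `eigenvalues`, `lag_steps`, `lag_ns`, `reversible`.
#' @export
estimate_markov_model <- function(counts, reversible = FALSE, prior_count = 0,
                                  lag_steps = 1L, lag_ns = NA_real_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || any(counts < 0)) {
    stop("counts must be a square non-negative matrix", call. = FALSE)
  }
  if (prior_count > 0) {
    conn <- (counts + t(counts)) > 0
    counts <- counts + prior_count * conn
  }
  g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  # largest SCC; ties resolved by total counts then lowest state index
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    tot <- vapply(best, function(b) {
      s <- comp$membership == b
      sum(counts[s, s])
    }, numeric(1L))
    best <- best[which.max(tot)]
  }
  active <- which(comp$membership == best[1L])
  if (length(active) == 0L || sum(counts[active, active]) == 0) {
    stop("no connected set with transition counts", call. = FALSE)
  }
  sub <- counts[active, active, drop = FALSE]
  if (reversible) {
    est <- reversible_mle(sub)
    T <- est$T
    stat <- est$stationary
  } else {
    T <- sub / rowSums(sub)
    stat <- stationary_distribution(T)
  }
  ev <- eigen(T, only.values = TRUE)$values
  ord <- order(-Re(ev), -abs(Im(ev)))
  structure(list(T = T, counts = sub, active_set = active,
                 stationary = stat, eigenvalues = ev[ord],
                 lag_steps = as.integer(lag_steps), lag_ns = lag_ns,
                 reversible = reversible),
            class = "markov_model")
}

#' Estimate a Markov model directly from a discrete trajectory
#'
#' Convenience wrapper: [count_matrix()] then [estimate_markov_model()].
#'
#' @inheritParams count_matrix
#' @inheritParams estimate_markov_model
#' @param frame_spacing_ns Frame spacing used to derive `lag_ns`.
#' @return A `markov_model`.
#' @export
markov_model <- function(dtraj, lag_steps = 1L, reversible = FALSE,
                         prior_count = 0, mode = "sliding",
                         frame_spacing_ns = NA_real_) {
  counts <- count_matrix(dtraj, lag_steps, mode)
  estimate_markov_model(counts, reversible, prior_count, lag_steps,
                        lag_ns = lag_steps * frame_spacing_ns)
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov state model: %d states (of %d), lag %d step(s)%s, %s\n",
              nrow(x$T), max(x$active_set), x$lag_steps,
              if (is.na(x$lag_ns)) "" else sprintf(" = %g ns", x$lag_ns),
              if (x$reversible) "reversible MLE" else "row-normalized"))
  cat("stationary distribution:", format(round(x$stationary, 4)), "\n")
  invisible(x)
}

#' @export
summary.markov_model <- function(object, ...) {
  ev <- Re(object$eigenvalues)
  its <- rep(NA_real_, length(ev))
  ok <- seq_along(ev) > 1L & ev > 0 & ev < 1 & abs(Im(object$eigenvalues)) < 1e-12
  tau <- if (is.na(object$lag_ns)) object$lag_steps else object$lag_ns
  its[ok] <- -tau / log(ev[ok])
  out <- list(n_states = nrow(object$T), lag_steps = object$lag_steps,
              lag_ns = object$lag_ns, eigenvalues = object$eigenvalues,
              implied_timescales = its[-1L], stationary = object$stationary)
  class(out) <- "summary.markov_model"
  out
}

#' @export
print.summary.markov_model <- function(x, ...) {
  cat(sprintf("Markov state model, %d states, lag %d step(s)\n",
              x$n_states, x$lag_steps))
  cat("eigenvalues: ", format(round(Re(x$eigenvalues), 4)), "\n")
  cat("implied timescales:", format(round(x$implied_timescales, 3)), "\n")
  invisible(x)
}

#' Simulate a trajectory from a fitted Markov model
#'
#' @param object A `markov_model`.
#' @param nsim Number of jumps.
#' @param seed RNG seed.
#' @param initial_state Starting state (index within the active set).
#' @param ... Unused.
#' @return A `discrete_trajectory` of length `nsim + 1`.
#' @export
simulate.markov_model <- function(object, nsim = 1000L, seed = 1L,
                                  initial_state = 1L, ...) {
  sample_markov_chain(object$T, nsim, initial_state, seed)
}

# symmetric half-weighted regularized inverse square root
inv_sqrt <- function(M, eps = 1e-12) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- e$values > eps * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (1 / sqrt(e$values[keep]) * t(e$vectors[, keep, drop = FALSE]))
}

#' VAMP-2 score of a discretization
#'
#' Scores how much slow kinetic variance a state partition captures: with
#' indicator features, the score is the sum of squared singular values of the
#' half-weighted Koopman matrix `C00^{-1/2} C0t Ctt^{-1/2}` estimated at the
#' given lag. It includes the trivial stationary singular value, so the score
#' is never below 1; an exactly Markovian two-state chain with
#' `T = [[1-a, a], [b, 1-b]]` scores `1 + (1-a-b)^2` in the long-data limit.
#'
#' @param dtraj Integer state labels.
#' @param n_states_eval Number of singular values summed (default: all
#'   states).
#' @param lag_steps Lag in steps.
#' @return Non-negative scalar score.
#' @export
vamp2_score <- function(dtraj, n_states_eval = NULL, lag_steps = 1L) {
  dtraj <- as.integer(dtraj)
  n <- max(dtraj)
  if (is.null(n_states_eval)) n_states_eval <- n
  L <- length(dtraj)
  if (L - lag_steps < n) {
    stop("fewer transition pairs than states; trajectory too short", call. = FALSE)
  }
  from <- dtraj[seq_len(L - lag_steps)]
  to <- dtraj[seq_len(L - lag_steps) + lag_steps]
  m <- length(from)
  C00 <- diag(tabulate(from, n) / m, n)
  Ctt <- diag(tabulate(to, n) / m, n)
  C0t <- count_matrix(dtraj, lag_steps, "sliding", n) / m
  K <- inv_sqrt(C00) %*% C0t %*% inv_sqrt(Ctt)
  s <- svd(K, nu = 0, nv = 0)$d
  sum(head(sort(s, decreasing = TRUE), n_states_eval)^2)
}

#' Implied timescales across lag times
#'
#' `t_i(tau) = -tau / log(lambda_i(tau))` for the non-unit eigenvalues of
#' the transition matrix estimated at each lag. Eigenvalues that are
#' non-positive or complex give `NA` with a warning (they carry no
#' timescale). Flat timescale curves across lags signal Markovianity.
#'
#' @param dtraj Integer state labels.
#' @param lag_list Integer lags (steps).
#' @param n_timescales Number of timescales to report (default: states - 1).
#' @param reversible Passed to the estimator.
#' @param frame_spacing_ns Converts lags to ns; `NA` reports timescales in
#'   steps.
#' @return Data frame with columns `lag_steps`, `lag_ns` and `ts1..tsK`
#'   (slowest first).
#' @export
implied_timescales <- function(dtraj, lag_list, n_timescales = NULL,
                               reversible = FALSE,
                               frame_spacing_ns = NA_real_) {
  n <- max(as.integer(dtraj))
  if (is.null(n_timescales)) n_timescales <- n - 1L
  warned <- FALSE
  rows <- lapply(lag_list, function(lag) {
    m <- markov_model(dtraj, lag, reversible, frame_spacing_ns = frame_spacing_ns)
    ev <- m$eigenvalues[-1L]
    ts <- rep(NA_real_, n_timescales)
    for (i in seq_len(min(length(ev), n_timescales))) {
      lam <- ev[i]
      if (abs(Im(lam)) < 1e-12 && Re(lam) > 0 && Re(lam) < 1) {
        tau <- if (is.na(frame_spacing_ns)) lag else lag * frame_spacing_ns
        ts[i] <- -tau / log(Re(lam))
      } else if (!warned) {
        warning("non-positive or complex eigenvalue: timescale reported as NA")
        warned <<- TRUE
      }
    }
    c(lag, if (is.na(frame_spacing_ns)) NA_real_ else lag * frame_spacing_ns, ts)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("lag_steps", "lag_ns", paste0("ts", seq_len(n_timescales)))
  out
}

# crisp PCCA partition used for CK coarse-graining; identity partition when
# the requested number of macrostates covers all microstates
ck_partition <- function(model, n_macro) {
  n <- nrow(model$T)
  if (is.null(n_macro) || n_macro >= n) {
    return(seq_len(n))
  }
  pcca(model, n_macro)$crisp_labels
}

# stationary-weighted coarse-grained transition matrix over crisp sets
coarse_grain_T <- function(T, stationary, labels) {
  macros <- sort(unique(labels))
  k <- length(macros)
  P <- matrix(0, k, k)
  for (I in seq_len(k)) {
    si <- labels == macros[I]
    wi <- stationary[si]
    for (J in seq_len(k)) {
      sj <- labels == macros[J]
      P[I, J] <- sum(wi * rowSums(T[si, sj, drop = FALSE])) / sum(wi)
    }
  }
  P
}

#' Chapman-Kolmogorov test
#'
#' Validates an estimated transition matrix `T(tau)` by comparing its powers
#' `T(tau)^j` against matrices re-estimated at the longer lags `j * tau`,
#' for `j = 1..k`, on macrostate self-transition probabilities
#' (coarse-grained by PCCA when `n_macro_for_test` is below the state
#' count). The agreement score per step is
#' `1 - mean(|predicted - estimated| / predicted)` clamped to \[0, 1\];
#' at `j = 1` both sides coincide, so the aggregate averages steps
#' `2..k`. A true Markov chain satisfies the identity exactly, so a
#' well-sampled Markovian trajectory scores near 1.
#'
#' @param dtraj Integer state labels.
#' @param lag_steps Estimation lag (steps).
#' @param k Longest prediction multiple (default 5).
#' @param n_macro_for_test Macrostates used for the comparison (default: all
#'   microstates).
#' @param reversible Passed to the estimator.
#' @return Object of class `ck_test`: list with `k`, `predicted` and
#'   `estimated` (matrices `k x n_macro` of self-transition probabilities),
#'   `agreement` (per step) and `aggregate`.
#' @export
ck_test <- function(dtraj, lag_steps, k = 5L, n_macro_for_test = NULL,
                    reversible = FALSE) {
  dtraj <- as.integer(dtraj)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(dtraj) <= k * lag_steps) {
    stop("trajectory too short to estimate at lag k * tau", call. = FALSE)
  }
  base <- markov_model(dtraj, lag_steps, reversible)
  labels <- ck_partition(base, n_macro_for_test)
  macros <- sort(unique(labels))
  nm <- length(macros)
  predicted <- estimated <- matrix(NA_real_, k, nm)
  Tj <- diag(nrow(base$T))
  for (j in seq_len(k)) {
    Tj <- Tj %*% base$T
    predicted[j, ] <- diag(coarse_grain_T(Tj, base$stationary, labels))
    mj <- markov_model(dtraj, j * lag_steps, reversible)
    # map the re-estimated model onto the base active set
    common <- intersect(base$active_set, mj$active_set)
    ib <- match(common, base$active_set)
    im <- match(common, mj$active_set)
    Tm <- matrix(0, nrow(base$T), nrow(base$T))
    Tm[ib, ib] <- mj$T[im, im]
    estimated[j, ] <- diag(coarse_grain_T(Tm, base$stationary, labels))
  }
  agreement <- vapply(seq_len(k), function(j) {
    dev <- abs(predicted[j, ] - estimated[j, ]) / pmax(predicted[j, ], 1e-12)
    min(max(1 - mean(dev), 0), 1)
  }, numeric(1L))
  aggregate <- if (k == 1L) 1 else mean(agreement[-1L])
  structure(list(k = k, predicted = predicted, estimated = estimated,
                 agreement = agreement, aggregate = aggregate,
                 macrostates = macros),
            class = "ck_test")
}

#' @export
print.ck_test <- function(x, ...) {
  cat(sprintf("Chapman-Kolmogorov test, k = %d, %d macrostate(s)\n",
              x$k, length(x$macrostates)))
  cat(sprintf("aggregate agreement: %.4f\n", x$aggregate))
  invisible(x)
}

#' Select the microstate count and lag time
#'
#' Scans `k_grid` with the VAMP-2 score of a k-means discretization. Because
#' the VAMP-2 score is non-decreasing under refinement, a literal argmax
#' always drifts to the largest k through estimation noise; the selected k is
#' therefore the smallest one whose score reaches the grid maximum within
#' `rel_tol_k` (the plateau start). The lag is then scanned with implied
#' timescales: the selected lag is the smallest one whose slowest timescale
#' varies by less than `rel_tol` over the next two grid points. If no lag
#' converges, the largest is returned with a warning.
#'
#' @param samples Matrix `n x d` of features to discretize.
#' @param k_grid Candidate microstate counts.
#' @param lag_grid Candidate lags (steps), increasing.
#' @param seed RNG seed for clustering.
#' @param score_lag Lag used for VAMP-2 scoring (steps).
#' @param rel_tol Relative flatness tolerance for the timescale heuristic.
#' @param rel_tol_k Relative tolerance defining the VAMP-2 score plateau.
#' @param reversible Passed to the estimators.
#' @return List with `k`, `lag_steps`, `vamp_scores` (data frame), and
#'   `its` (implied-timescale table over `lag_grid`).
#' @export
select_hyperparameters <- function(samples, k_grid, lag_grid, seed = 1L,
                                   score_lag = min(lag_grid), rel_tol = 0.10,
                                   rel_tol_k = 0.01, reversible = FALSE) {
  stopifnot(length(k_grid) >= 1L, length(lag_grid) >= 1L)
  x <- as.matrix(samples)
  k_grid <- sort(k_grid)
  scores <- vapply(k_grid, function(k) {
    cl <- kmeans_cluster(x, k, seed = seed)
    vamp2_score(cl$assignments, lag_steps = score_lag)
  }, numeric(1L))
  k_best <- k_grid[which(scores >= (1 - rel_tol_k) * max(scores))[1L]]
  cl <- kmeans_cluster(x, k_best, seed = seed)
  its <- implied_timescales(cl$assignments, lag_grid, n_timescales = 1L,
                            reversible = reversible)
  lag_grid <- sort(lag_grid)
  lag_best <- NA_integer_
  t2 <- its$ts1
  if (length(lag_grid) >= 3L) {
    for (i in seq_len(length(lag_grid) - 2L)) {
      window <- t2[i:(i + 2L)]
      if (all(is.finite(window)) &&
          max(abs(window[-1L] - window[1L])) < rel_tol * abs(window[1L])) {
        lag_best <- lag_grid[i]
        break
      }
    }
  }
  if (is.na(lag_best)) {
    warning("no lag with converged timescales; returning the largest lag")
    lag_best <- lag_grid[length(lag_grid)]
  }
  list(k = k_best, lag_steps = lag_best,
       vamp_scores = data.frame(k = k_grid, vamp2 = scores),
       its = its, dtraj = cl$assignments)
}
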