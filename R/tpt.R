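# Macrostate coarse-graining (PCCA+) and transition-path-theory flux
# analysis: committors, gross/net flux, pathway decomposition.

#' PCCA+ macrostate partition
#'
#' Perron-cluster cluster analysis: the top `n_macrostates` right
#' eigenvectors of the transition matrix span an (n-1)-simplex whose
#' vertices correspond to metastable states. Vertices are located with the
#' inner-simplex algorithm (successive orthogonal deflation) and fuzzy
#' memberships follow from expressing each microstate in vertex coordinates;
#' small negative coefficients are clamped to zero and rows renormalized.
#' Crisp labels are the membership argmax.
#'
#' @param model A `markov_model`. A non-reversible model is accepted with a
#'   warning (PCCA+ assumes a real spectrum).
#' @param n_macrostates Number of macrostates (>= 1). Errors, naming the
#'   usable maximum, if the top eigenvalues are not real.
#' @return Object of class `macrostate_partition`: list with `memberships`
#'   (`n_micro x n_macro`, rows sum to 1), `crisp_labels`, `names`.
#' @export
pcca <- function(model, n_macrostates) {
  stopifnot(inherits(model, "markov_model"))
  n_macrostates <- as.integer(n_macrostates)
  n <- nrow(model$T)
  stopifnot(n_macrostates >= 1L, n_macrostates <= n)
  if (!model$reversible) {
    db <- max(abs(model$stationary * model$T -
                  t(model$stationary * model$T)))
    if (db > 1e-8) {
      warning("model is not reversible; PCCA+ run on the non-symmetric matrix")
    }
  }
  if (n_macrostates == 1L) {
    return(structure(list(memberships = matrix(1, n, 1L),
                          crisp_labels = rep(1L, n),
                          names = "S1"),
                     class = "macrostate_partition"))
  }
  e <- eigen(model$T)
  ord <- order(-Re(e$values))
  vals <- e$values[ord]
  n_real <- which(abs(Im(vals)) > 1e-8)
  usable <- if (length(n_real)) n_real[1L] - 1L else n
  if (n_macrostates > usable) {
    stop(sprintf("top eigenvalues are complex beyond %d; at most %d macrostates usable",
                 usable, usable), call. = FALSE)
  }
  X <- Re(e$vectors[, ord[seq_len(n_macrostates)], drop = FALSE])
  X[, 1L] <- 1
  # inner-simplex vertex search
  verts <- integer(n_macrostates)
  Y <- X
  verts[1L] <- which.max(rowSums(Y^2))
  for (j in 2:n_macrostates) {
    v <- Y[verts[j - 1L], ]
    nv <- sqrt(sum(v^2))
    if (nv > 0) {
      Y <- Y - (Y %*% v / nv) %*% t(v / nv)
    }
    verts[j] <- which.max(rowSums(Y^2))
  }
  chi <- X %*% solve(X[verts, , drop = FALSE])
  chi[chi < 0] <- 0
  rs <- rowSums(chi)
  rs[rs == 0] <- 1
  chi <- chi / rs
  crisp <- max.col(chi, ties.method = "first")
  if (length(unique(crisp)) < n_macrostates) {
    stop(sprintf("crisp assignment leaves empty macrostates; at most %d macrostates usable",
                 length(unique(crisp))), call. = FALSE)
  }
  structure(list(memberships = chi, crisp_labels = crisp,
                 names = paste0("S", seq_len(n_macrostates))),
            class = "macrostate_partition")
}

#' Forward and backward committor probabilities
#'
#' The forward committor `q+_i` is the probability that a trajectory at
#' microstate i reaches the sink set B before the source set A. It satisfies
#' the boundary conditions `q+ = 0` on A, `q+ = 1` on B and, in between, the
#' linear system `q+_i = sum_{j in B} T_ij + sum_{j notin A u B} T_ij q+_j`
#' (solved densely). The backward committor is reported as `q- = 1 - q+`,
#' which is exact for reversible dynamics.
#'
#' @param model A `markov_model`.
#' @param A,B Disjoint, non-empty microstate index sets (within the active
#'   set).
#' @return Object of class `committor_result`: list with `q_plus`,
#'   `q_minus`, `A`, `B`.
#' @export
committor <- function(model, A, B) {
  stopifnot(inherits(model, "markov_model"))
  n <- nrow(model$T)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0L || length(B) == 0L) {
    stop("A and B must be non-empty", call. = FALSE)
  }
  if (length(intersect(A, B))) stop("A and B must be disjoint", call. = FALSE)
  if (any(c(A, B) < 1L) || any(c(A, B) > n)) {
    stop("A and B must index states of the active set", call. = FALSE)
  }
  q <- numeric(n)
  q[B] <- 1
  C <- setdiff(seq_len(n), c(A, B))
  if (length(C)) {
    M <- diag(length(C)) - model$T[C, C, drop = FALSE]
    b <- rowSums(model$T[C, B, drop = FALSE])
    sol <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(sol)) {
      warning("singular committor system (B unreachable?); q+ set to 0 outside B")
      sol <- numeric(length(C))
    }
    q[C] <- pmin(pmax(sol, 0), 1)
  }
  structure(list(q_plus = q, q_minus = 1 - q, A = A, B = B),
            class = "committor_result")
}

#' Transition-path-theory flux network
#'
#' Gross reactive flux `f_ij = rho_i q-_i T_ij q+_j` (diagonal zeroed), net
#' flux `f+_ij = max(f_ij - f_ji, 0)` and total A -> B flux
#' `F = sum_{i in A} sum_j f+_ij`. Outside the endpoint sets the net flux is
#' conserved (inflow equals outflow).
#'
#' @param model A `markov_model`.
#' @param committors A [committor()] result on the same active set.
#' @return Object of class `flux_network`: list with `gross_flux`,
#'   `net_flux`, `total_flux`, `stationary`, `q_plus`, `q_minus`, `A`, `B`.
#' @export
flux_network <- function(model, committors) {
  stopifnot(inherits(model, "markov_model"),
            inherits(committors, "committor_result"))
  n <- nrow(model$T)
  if (length(committors$q_plus) != n) {
    stop("committors and model disagree on the state space", call. = FALSE)
  }
  rho <- model$stationary
  qp <- committors$q_plus
  qm <- committors$q_minus
  gross <- (rho * qm) * model$T * rep(qp, each = n)
  diag(gross) <- 0
  net <- pmax(gross - t(gross), 0)
  total <- sum(net[committors$A, , drop = FALSE])
  structure(list(gross_flux = gross, net_flux = net, total_flux = total,
                 stationary = rho, q_plus = qp, q_minus = qm,
                 A = committors$A, B = committors$B),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat(sprintf("flux network: %d states, |A| = %d, |B| = %d, total flux %.6g\n",
              nrow(x$net_flux), length(x$A), length(x$B), x$total_flux))
  invisible(x)
}

# widest (max-bottleneck) path from any state in A to any state in B over
# the positive edges of `net`; returns NULL when B is unreachable
widest_path <- function(net, A, B) {
  n <- nrow(net)
  width <- rep(-Inf, n)
  prev <- rep(NA_integer_, n)
  width[A] <- Inf
  visited <- rep(FALSE, n)
  repeat {
    cand <- which(!visited & width > 0)
    if (!length(cand)) break
    u <- cand[which.max(width[cand])]
    visited[u] <- TRUE
    if (u %in% B) break
    for (v in which(net[u, ] > 0)) {
      w <- min(width[u], net[u, v])
      if (w > width[v]) {
        width[v] <- w
        prev[v] <- u
      }
    }
  }
  reached <- B[is.finite(width[B]) & width[B] > 0]
  if (!length(reached)) return(NULL)
  end <- reached[which.max(width[reached])]
  path <- end
  while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
  list(path = path, bottleneck = width[end])
}

# all simple A->B paths over positive edges (DFS)
enumerate_paths <- function(net, A, B) {
  paths <- list()
  n <- nrow(net)
  dfs <- function(path) {
    u <- path[length(path)]
    if (u %in% B) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in which(net[u, ] > 0)) {
      if (!(v %in% path) && !(v %in% A)) dfs(c(path, v))
    }
  }
  for (a in A) dfs(a)
  paths
}

#' Decompose the reactive flux into pathways
#'
#' `mode = "bottleneck_greedy"` repeatedly extracts the strongest-bottleneck
#' A -> B path from the net-flux graph, assigns it its bottleneck flux,
#' subtracts, and repeats until the total flux is exhausted (or `max_paths`
#' is reached; the remainder is reported as `residual_flux`).
#' `mode = "exhaustive"` enumerates every simple A -> B path (state count
#' <= 12) with its bottleneck capacity on the unmodified net-flux graph; it
#' serves as the reference for small systems. Path probabilities are
#' `P_i = f_i / sum_j f_j` (greedy: `f_i / total_flux`).
#'
#' @param flux A [flux_network()].
#' @param max_paths Cap on extracted paths (greedy mode).
#' @param mode `"bottleneck_greedy"` or `"exhaustive"`.
#' @return Object of class `path_decomposition`: data frame `paths` (columns
#'   `path` string like `"1->2->4"`, `flux`, `probability`), plus
#'   `residual_flux` and `total_flux`.
#' @export
decompose_paths <- function(flux, max_paths = Inf,
                            mode = c("bottleneck_greedy", "exhaustive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(flux, "flux_network"))
  A <- flux$A; B <- flux$B
  total <- flux$total_flux
  fmt <- function(p) paste(p, collapse = "->")
  if (mode == "exhaustive") {
    if (nrow(flux$net_flux) > 12L) {
      stop("exhaustive enumeration is limited to <= 12 states; use bottleneck_greedy",
           call. = FALSE)
    }
    ps <- enumerate_paths(flux$net_flux, A, B)
    fl <- vapply(ps, function(p) {
      min(flux$net_flux[cbind(p[-length(p)], p[-1L])])
    }, numeric(1L))
    ord <- order(-fl)
    ps <- ps[ord]; fl <- fl[ord]
    prob <- if (sum(fl) > 0) fl / sum(fl) else rep(0, length(fl))
    paths <- data.frame(path = vapply(ps, fmt, character(1L)),
                        flux = fl, probability = prob,
                        stringsAsFactors = FALSE)
    return(structure(list(paths = paths, residual_flux = 0,
                          total_flux = total, mode = mode),
                     class = "path_decomposition"))
  }
  net <- flux$net_flux
  rows <- list()
  assigned <- 0
  while (assigned < total - 1e-14 * max(total, 1) && length(rows) < max_paths) {
    wp <- widest_path(net, A, B)
    if (is.null(wp) || wp$bottleneck <= 0) break
    edges <- cbind(wp$path[-length(wp$path)], wp$path[-1L])
    net[edges] <- net[edges] - wp$bottleneck
    assigned <- assigned + wp$bottleneck
    rows[[length(rows) + 1L]] <- data.frame(path = fmt(wp$path),
                                            flux = wp$bottleneck,
                                            stringsAsFactors = FALSE)
  }
  paths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), flux = numeric())
  paths$probability <- if (total > 0) paths$flux / total else
    rep(0, nrow(paths))
  structure(list(paths = paths, residual_flux = max(total - assigned, 0),
                 total_flux = total, mode = mode),
            class = "path_decomposition")
}

#' @export
print.path_decomposition <- function(x, ...) {
  cat(sprintf("path decomposition (%s): total flux %.6g, residual %.3g\n",
              x$mode, x$total_flux, x$residual_flux))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Macrostate-level flux summary
#'
#' Aggregates the microstate net flux by crisp macrostate labels and renders
#' endpoint-anchored pathway strings: `SA` is the macrostate with the
#' highest stationary-weighted backward-committor density (the source
#' basin), `SB` the highest forward-committor density (the sink basin), and
#' the remaining macrostates keep `S#` names. The dominant pathway and the
#' share of total flux it carries are extracted by greedy decomposition of
#' the coarse-grained network.
#'
#' @param flux A [flux_network()].
#' @param partition A [pcca()] partition over the same microstates.
#' @return List with `coarse_flux` (macro net-flux matrix with SA/SB/S#
#'   dimnames), `names` (per macrostate), `paths` (macro pathway table with
#'   `path` strings, flux, probability), `dominant` (string, e.g.
#'   `"SA->S3->SB"`), `dominant_share` (its probability).
#' @export
macrostate_flux_summary <- function(flux, partition) {
  stopifnot(inherits(flux, "flux_network"),
            inherits(partition, "macrostate_partition"))
  labels <- partition$crisp_labels
  n <- nrow(flux$net_flux)
  if (length(labels) != n) {
    stop("partition does not cover the flux state space", call. = FALSE)
  }
  k <- max(labels)
  coarse <- matrix(0, k, k)
  for (I in seq_len(k)) for (J in seq_len(k)) {
    if (I != J) {
      coarse[I, J] <- sum(flux$net_flux[labels == I, labels == J, drop = FALSE])
    }
  }
  rho <- flux$stationary
  dens <- function(q) vapply(seq_len(k), function(I) {
    s <- labels == I
    sum(rho[s] * q[s]) / sum(rho[s])
  }, numeric(1L))
  sa <- which.max(dens(flux$q_minus))
  sb_cand <- setdiff(order(-dens(flux$q_plus)), sa)
  sb <- sb_cand[1L]
  nm <- paste0("S", seq_len(k))
  nm[sa] <- "SA"; nm[sb] <- "SB"
  others <- setdiff(seq_len(k), c(sa, sb))
  nm[others] <- paste0("S", seq_along(others))
  dimnames(coarse) <- list(nm, nm)
  # net-of-net at macro level, then greedy pathway extraction SA -> SB
  coarse_net <- pmax(coarse - t(coarse), 0)
  total <- sum(coarse_net[sa, ])
  net <- coarse_net
  rows <- list()
  assigned <- 0
  while (assigned < total - 1e-14 * max(total, 1) && length(rows) < 64L) {
    wp <- widest_path(net, sa, sb)
    if (is.null(wp) || wp$bottleneck <= 0) break
    edges <- cbind(wp$path[-length(wp$path)], wp$path[-1L])
    net[edges] <- net[edges] - wp$bottleneck
    assigned <- assigned + wp$bottleneck
    rows[[length(rows) + 1L]] <-
      data.frame(path = paste(nm[wp$path], collapse = "->"),
                 flux = wp$bottleneck, stringsAsFactors = FALSE)
  }
  paths <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), flux = numeric())
  paths$probability <- if (total > 0) paths$flux / total else
    rep(0, nrow(paths))
  dominant <- if (nrow(paths)) paths$path[which.max(paths$flux)] else NA_character_
  share <- if (nrow(paths)) max(paths$probability) else NA_real_
  list(coarse_flux = coarse, names = nm, paths = paths,
       dominant = dominant, dominant_share = share)
}
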