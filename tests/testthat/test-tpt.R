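# PCCA+ coarse-graining and transition-path-theory flux analysis.

three_state_T <- matrix(c(0.5, 0.5, 0,
                          0.25, 0.5, 0.25,
                          0, 0.5, 0.5), 3, 3, byrow = TRUE)

test_that("PCCA recovers exact and nearly-uncoupled block structure", {
  # exact 2-block chain
  Tb <- matrix(0, 4, 4)
  Tb[1:2, 1:2] <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  Tb[3:4, 3:4] <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  m <- as_markov_model(Tb)
  p <- pcca(m, 2)
  expect_equal(length(unique(p$crisp_labels[1:2])), 1L)
  expect_equal(length(unique(p$crisp_labels[3:4])), 1L)
  expect_false(p$crisp_labels[1] == p$crisp_labels[3])
  expect_equal(rowSums(p$memberships), rep(1, 4), tolerance = 1e-9)

  p1 <- pcca(m, 1)
  expect_equal(p1$memberships, matrix(1, 4, 1))

  # nearly-uncoupled 3-block chain, coupling 1e-3
  blocks <- list(1:2, 3:4, 5:6)
  Tn <- matrix(1e-3, 6, 6)
  for (b in blocks) Tn[b, b] <- 0.5
  Tn <- Tn / rowSums(Tn)
  mn <- as_markov_model(Tn)
  pn <- pcca(mn, 3)
  lab <- pn$crisp_labels
  for (b in blocks) expect_equal(length(unique(lab[b])), 1L)
  expect_equal(length(unique(vapply(blocks, function(b) lab[b[1]], integer(1)))),
               3L)
  # invariance to state relabelling
  perm <- c(5L, 6L, 1L, 2L, 3L, 4L)
  mp <- as_markov_model(Tn[perm, perm])
  lp <- pcca(mp, 3)$crisp_labels
  expect_equal(length(unique(paste(lab[perm], lp))), 3L)
})

test_that("committors obey boundary conditions and the gambler's-ruin form", {
  Tg <- matrix(0, 5, 5)
  Tg[1, 1:2] <- 0.5; Tg[5, 4:5] <- 0.5
  for (i in 2:4) { Tg[i, i - 1] <- 0.5; Tg[i, i + 1] <- 0.5 }
  m <- as_markov_model(Tg)
  cm <- committor(m, A = 1, B = 5)
  expect_equal(cm$q_plus, c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(cm$q_minus, 1 - cm$q_plus)
  expect_error(committor(m, A = 1:2, B = 2:3), "disjoint")
  expect_error(committor(m, A = integer(0), B = 3), "non-empty")
})

test_that("committor is monotone along birth-death chains", {
  for (seed in 1:5) {
    n <- 7
    p <- with_seed_test(seed, runif(n - 1, 0.2, 0.8))
    T <- matrix(0, n, n)
    T[1, 1] <- 1 - p[1]; T[1, 2] <- p[1]
    T[n, n] <- p[n - 1]; T[n, n - 1] <- 1 - p[n - 1]
    for (i in 2:(n - 1)) {
      T[i, i + 1] <- p[i]
      T[i, i - 1] <- 1 - p[i]
    }
    m <- as_markov_model(T, reversible = TRUE)
    q <- committor(m, 1, n)$q_plus
    expect_true(all(diff(q) >= -1e-12))
  }
})

test_that("the worked three-state flux example is reproduced end to end", {
  m <- as_markov_model(three_state_T)
  expect_equal(m$stationary, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  cm <- committor(m, 1, 3)
  expect_equal(cm$q_plus, c(0, 0.5, 1))
  fx <- flux_network(m, cm)
  expect_equal(fx$net_flux[1, 2], 0.0625, tolerance = 1e-12)
  expect_equal(fx$net_flux[2, 3], 0.0625, tolerance = 1e-12)
  expect_equal(fx$total_flux, 0.0625, tolerance = 1e-12)
})

test_that("unreachable sinks carry zero flux", {
  Tb <- matrix(0, 4, 4)
  Tb[1:2, 1:2] <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)
  Tb[3:4, 3:4] <- matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2)
  m <- as_markov_model(Tb)
  cm <- suppressWarnings(committor(m, 1, 4))
  fx <- flux_network(m, cm)
  expect_equal(fx$total_flux, 0)
})

test_that("net flux conserves at intermediates and has disjoint support", {
  for (seed in 1:100) {
    rt <- random_reversible_T(6, seed)
    m <- as_markov_model(rt$T, rt$stationary)
    A <- 1L; B <- 6L
    fx <- flux_network(m, committor(m, A, B))
    net <- fx$net_flux
    expect_true(all(pmin(net, t(net)) == 0))      # complementarity
    for (i in setdiff(1:6, c(A, B))) {
      expect_lt(abs(sum(net[, i]) - sum(net[i, ])), 1e-10)
    }
    expect_lt(abs(sum(net[A, ]) - sum(net[, B])), 1e-10)
  }
})

test_that("a linear chain yields a single pathway carrying all flux", {
  m <- as_markov_model(three_state_T)
  fx <- flux_network(m, committor(m, 1, 3))
  for (mode in c("exhaustive", "bottleneck_greedy")) {
    dec <- decompose_paths(fx, mode = mode)
    expect_equal(nrow(dec$paths), 1L)
    expect_equal(dec$paths$path, "1->2->3")
    expect_equal(dec$paths$probability, 1.0)
  }
})

test_that("a symmetric diamond splits the flux half and half", {
  Td <- matrix(c(0.5, 0.25, 0.25, 0,
                 0.25, 0.5, 0, 0.25,
                 0.25, 0, 0.5, 0.25,
                 0, 0.25, 0.25, 0.5), 4, 4, byrow = TRUE)
  m <- as_markov_model(Td)
  fx <- flux_network(m, committor(m, 1, 4))
  dec <- decompose_paths(fx, mode = "exhaustive")
  expect_equal(nrow(dec$paths), 2L)
  expect_equal(sort(dec$paths$path), c("1->2->4", "1->3->4"))
  expect_equal(dec$paths$probability, c(0.5, 0.5))
  greedy <- decompose_paths(fx, mode = "bottleneck_greedy")
  expect_equal(sum(greedy$paths$flux), fx$total_flux, tolerance = 1e-12)
})

test_that("greedy decomposition exhausts the flux and matches enumeration", {
  for (seed in 1:10) {
    rt <- random_reversible_T(6, seed + 200)
    m <- as_markov_model(rt$T, rt$stationary)
    fx <- flux_network(m, committor(m, 1, 6))
    greedy <- decompose_paths(fx, mode = "bottleneck_greedy")
    expect_lt(abs(sum(greedy$paths$flux) - fx$total_flux), 1e-10)
    expect_lt(greedy$residual_flux, 1e-10)
    expect_lte(sum(greedy$paths$probability), 1 + 1e-9)
    exh <- decompose_paths(fx, mode = "exhaustive")
    # the strongest-bottleneck channel is ranked first in both modes
    expect_equal(greedy$paths$path[1], exh$paths$path[1])
    # every path runs source to sink without revisits
    for (p in strsplit(greedy$paths$path, "->")) {
      expect_equal(p[1], "1")
      expect_equal(p[length(p)], "6")
      expect_equal(anyDuplicated(p), 0L)
    }
  }
  # exhaustive mode refuses large systems
  rt <- random_reversible_T(13, 1)
  m <- as_markov_model(rt$T, rt$stationary)
  fx <- flux_network(m, committor(m, 1, 13))
  expect_error(decompose_paths(fx, mode = "exhaustive"), "bottleneck_greedy")
})

test_that("macrostate summaries aggregate flux and name endpoint states", {
  m <- as_markov_model(three_state_T)
  fx <- flux_network(m, committor(m, 1, 3))
  part <- structure(list(memberships = diag(3), crisp_labels = 1:3,
                         names = paste0("S", 1:3)),
                    class = "macrostate_partition")
  summ <- macrostate_flux_summary(fx, part)
  expect_equal(summ$dominant, "SA->S1->SB")
  expect_equal(summ$dominant_share, 1.0)
  expect_equal(sum(summ$paths$flux), fx$total_flux, tolerance = 1e-12)
  # brute-force aggregation parity on a random partition
  rt <- random_reversible_T(6, 33)
  m6 <- as_markov_model(rt$T, rt$stationary)
  fx6 <- flux_network(m6, committor(m6, 1, 6))
  labels <- c(1L, 1L, 2L, 2L, 3L, 3L)
  part6 <- structure(list(memberships = diag(3)[labels, ],
                          crisp_labels = labels, names = paste0("S", 1:3)),
                     class = "macrostate_partition")
  s6 <- macrostate_flux_summary(fx6, part6)
  brute <- matrix(0, 3, 3)
  for (i in 1:6) for (j in 1:6) {
    if (labels[i] != labels[j]) {
      brute[labels[i], labels[j]] <- brute[labels[i], labels[j]] +
        fx6$net_flux[i, j]
    }
  }
  expect_equal(unname(s6$coarse_flux), brute, tolerance = 1e-12)
})
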