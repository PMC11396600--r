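# Discretization and Markov-model estimation/validation.

test_that("k-means hits the exact limits and parities the reference library", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  r <- kmeans_cluster(pts, 4, seed = 1)
  expect_equal(r$inertia, 0)
  expect_equal(pts[order(pts[, 1], pts[, 2]), ],
               r$centers[order(r$centers[, 1], r$centers[, 2]), ],
               ignore_attr = TRUE)
  r1 <- kmeans_cluster(pts, 1, seed = 1)
  expect_equal(r1$centers[1, ], colMeans(pts), ignore_attr = TRUE)

  blobs <- with_seed_test(4, rbind(matrix(rnorm(400, sd = 1), 200, 2),
                                   matrix(rnorm(400, 20, sd = 1), 200, 2)))
  truth <- rep(1:2, each = 200)
  r2 <- kmeans_cluster(blobs, 2, seed = 9)
  agree <- max(mean((r2$assignments == 1) == (truth == 1)),
               mean((r2$assignments == 2) == (truth == 1)))
  expect_equal(agree, 1)
  ref <- with_seed_test(11, kmeans(blobs, 2, nstart = 10))
  expect_equal(r2$inertia, ref$tot.withinss, tolerance = 1e-6)
  expect_error(kmeans_cluster(pts, 5, seed = 1), "distinct")
})

test_that("microstate assignment uses nearest centre with low-index ties", {
  centers <- matrix(c(0, 1, 2, 4, 2, 9), ncol = 1)  # centres 3 and 5 both at 2
  expect_equal(as.integer(assign_microstates(matrix(2), centers)), 3L)
  expect_equal(as.integer(assign_microstates(matrix(3), centers)),
               3L)  # equidistant between 2 and 4 -> lower index
  expect_equal(as.integer(assign_microstates(matrix(9), centers)), 6L)
  expect_error(assign_microstates(matrix(1, 1, 2), centers), "dimensionality")
})

test_that("count matrices match hand counts", {
  d <- c(1L, 2L, 2L, 1L, 3L)
  C <- count_matrix(d, 1)
  # pairs: 1->2, 2->2, 2->1, 1->3
  expect_equal(C, matrix(c(0, 1, 1,
                           1, 1, 0,
                           0, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(sum(C), length(d) - 1)
  C2 <- count_matrix(c(1L, 2L, 1L, 2L), 2)
  expect_equal(diag(C2), c(1, 1))
  expect_equal(sum(C2), 2)
  Cs <- count_matrix(d, 2, mode = "strided")
  expect_equal(sum(Cs), 2)
  expect_error(count_matrix(d, 5), "length")
})

test_that("transition-matrix estimation is exact on symmetric counts", {
  C <- matrix(c(9, 1, 1, 9), 2, 2)
  for (rev in c(FALSE, TRUE)) {
    m <- estimate_markov_model(C, reversible = rev)
    expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-9)
    expect_equal(sum(m$stationary), 1)
    expect_equal(drop(m$stationary %*% m$T), m$stationary, tolerance = 1e-8)
    expect_equal(Re(m$eigenvalues[1]), 1, tolerance = 1e-10)
  }
})

test_that("the reversible estimator satisfies detailed balance everywhere", {
  for (seed in 1:5) {
    C <- with_seed_test(seed, matrix(rpois(25, 15) + 1, 5, 5))
    m <- estimate_markov_model(C, reversible = TRUE)
    F <- m$stationary * m$T
    expect_lt(max(abs(F - t(F))), 1e-8)
    expect_lt(max(abs(rowSums(m$T) - 1)), 1e-10)
  }
})

test_that("the reversible MLE matches a brute-force constrained optimizer", {
  C <- with_seed_test(8, matrix(rpois(9, 25) + 1, 3, 3))
  m <- estimate_markov_model(C, reversible = TRUE)
  # oracle: maximize sum C_ij log T_ij over symmetric flows x (6 parameters)
  nll <- function(par) {
    x <- matrix(0, 3, 3)
    x[upper.tri(x, diag = TRUE)] <- exp(par)
    x <- x + t(x) - diag(diag(x))
    T <- x / rowSums(x)
    -sum(C * log(T))
  }
  fit <- optim(rep(0, 6), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  x <- matrix(0, 3, 3)
  x[upper.tri(x, diag = TRUE)] <- exp(fit$par)
  x <- x + t(x) - diag(diag(x))
  T_oracle <- x / rowSums(x)
  expect_equal(m$T, T_oracle, tolerance = 1e-5)
  expect_lte(-sum(C * log(T_oracle)) - (-sum(C * log(m$T))), 1e-6)
})

test_that("disconnected states are trimmed to the largest strong component", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 10
  C[3, 4] <- 2          # 3 -> 4 one-way; {3},{4} are their own SCCs
  m <- estimate_markov_model(C)
  expect_equal(m$active_set, 1:2)
  expect_equal(dim(m$T), c(2L, 2L))
  expect_error(estimate_markov_model(matrix(0, 2, 2)), "connected")
})

test_that("VAMP-2 scores approach their spectral limits", {
  T2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  d <- sample_markov_chain(T2, 200000, 1, seed = 2)
  expect_equal(vamp2_score(d, lag_steps = 1), 1 + 0.8^2, tolerance = 0.02)
  iid <- with_seed_test(3, sample.int(3, 50000, replace = TRUE))
  expect_equal(vamp2_score(iid, lag_steps = 1), 1, tolerance = 0.01)
  for (seed in 1:5) {
    dr <- with_seed_test(seed, sample.int(4, 2000, replace = TRUE))
    expect_gte(vamp2_score(dr, lag_steps = 1), 1 - 1e-9)
  }
})

test_that("VAMP-2 of the true partition beats any merged partition", {
  T3 <- matrix(c(0.95, 0.04, 0.01,
                 0.04, 0.92, 0.04,
                 0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  d <- sample_markov_chain(T3, 100000, 1, seed = 5)
  full <- vamp2_score(d, lag_steps = 1)
  for (merge in list(c(1L, 1L, 2L), c(1L, 2L, 2L), c(1L, 2L, 1L))) {
    merged <- merge[d]
    expect_gte(full, vamp2_score(merged, lag_steps = 1) - 1e-9)
  }
})

test_that("implied timescales recover the spectral closed form", {
  a <- 0.1
  T2 <- matrix(c(1 - a, a, a, 1 - a), 2, 2, byrow = TRUE)
  d <- sample_markov_chain(T2, 100000, 1, seed = 6)
  its <- implied_timescales(d, c(1, 2, 5, 10))
  truth <- -1 / log(1 - 2 * a)        # 4.4814 steps
  expect_equal(its$ts1[1], truth, tolerance = 0.1)
  # Markovian data: flat across lags
  expect_lt(max(abs(its$ts1 - its$ts1[1])) / its$ts1[1], 0.1)
  # in ns when a spacing is given
  its_ns <- implied_timescales(d, 1, frame_spacing_ns = 0.1)
  expect_equal(its_ns$ts1[1], 0.1 * its$ts1[1], tolerance = 1e-9)
})

test_that("the CK test is exact at k = 1 and near 1 on Markovian data", {
  T3 <- matrix(c(0.95, 0.04, 0.01,
                 0.04, 0.92, 0.04,
                 0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  d <- sample_markov_chain(T3, 100000, 1, seed = 1)
  ck1 <- ck_test(d, 1, k = 1)
  expect_equal(ck1$aggregate, 1)
  expect_equal(ck1$agreement[1], 1)
  ck <- ck_test(d, 1, k = 5)
  expect_gte(ck$aggregate, 0.95)
  expect_error(ck_test(d[1:4], 1, k = 5), "too short")
  # true Chapman-Kolmogorov identity: exact matrix powers agree
  P5 <- T3 %*% T3 %*% T3 %*% T3 %*% T3
  m <- as_markov_model(T3)
  expect_equal(P5, with(m, {
    P <- diag(3); for (i in 1:5) P <- P %*% T; P
  }), tolerance = 1e-12)
})

test_that("hyperparameter selection recovers the generative state count", {
  T3 <- matrix(c(0.95, 0.04, 0.01,
                 0.04, 0.92, 0.04,
                 0.01, 0.04, 0.95), 3, 3, byrow = TRUE)
  centers_true <- c(-5, 0, 5)
  wins <- 0L
  for (seed in 1:5) {
    d <- sample_markov_chain(T3, 20000, 1, seed = seed)
    x <- matrix(centers_true[d] +
                  with_seed_test(seed + 50, rnorm(length(d), sd = 0.4)))
    sel <- select_hyperparameters(x, k_grid = 2:5, lag_grid = c(1, 2, 5),
                                  seed = seed)
    if (sel$k == 3L) wins <- wins + 1L
    expect_equal(sel$lag_steps, 1L)  # Markovian: smallest lag converges
  }
  expect_gte(wins, 3L)
})

test_that("lag-time bookkeeping converts ns to steps and durations to frames", {
  expect_identical(lag_to_steps(1.2, 0.1), 12L)
  expect_identical(duration_to_frames(450, 0.1), 4500L)
  expect_error(lag_to_steps(0.25, 0.1), "multiple")
})
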