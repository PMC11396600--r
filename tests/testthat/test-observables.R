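# Structural observables against closed forms and independent oracles.

random_rotation <- function(seed) {
  with_seed_test(seed, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  })
}

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(10)
  a <- matrix(rnorm(30), 10, 3)
  f <- kabsch_superpose(a, a)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation(4)
  b <- a %*% R + rep(c(3, -1, 7), each = 10)
  f2 <- kabsch_superpose(b, a)
  expect_equal(f2$rmsd, 0, tolerance = 1e-9)
  expect_equal(f2$fitted, a, tolerance = 1e-9)
  expect_equal(det(f2$rotation), 1, tolerance = 1e-12)
  expect_error(kabsch_superpose(a[1:5, ], a), "same number")
})

raw_rmsd_oracle <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

test_that("Kabsch RMSD agrees with an independent quaternion oracle", {
  for (seed in 1:20) {
    x <- with_seed_test(seed, matrix(rnorm(30), 10, 3))
    y <- with_seed_test(seed + 100, matrix(rnorm(30), 10, 3))
    f <- kabsch_superpose(x, y)
    expect_equal(f$rmsd, horn_rmsd(x, y), tolerance = 1e-9)
    expect_equal(det(f$rotation), 1, tolerance = 1e-12)
    # fitting never increases the RMSD
    expect_lte(f$rmsd, raw_rmsd_oracle(x, y) + 1e-12)
  }
})

test_that("RMSD series vanishes for rigid-body-moved copies", {
  topo <- topology(rep("CA", 8), rep("C", 8), 1:8)
  base <- with_seed_test(7, matrix(rnorm(24, sd = 5), 8, 3))
  coords <- array(NA_real_, c(5, 8, 3))
  coords[1, , ] <- base
  for (f in 2:5) {
    coords[f, , ] <- base %*% random_rotation(f) + rep(c(f, -f, 2 * f), each = 8)
  }
  tr <- trajectory(topo, coords)
  s <- rmsd_series(tr)
  expect_equal(s$value, rep(0, 5), tolerance = 1e-8)
  expect_equal(s$value[1], 0, tolerance = 1e-12)
})

test_that("fitted RMSD tracks the no-superposition oracle on Gaussian noise", {
  ref <- with_seed_test(3, matrix(rnorm(60, sd = 10), 20, 3))
  g <- gaussian_ensemble(ref, site_sd = 0.6, cfg = generator_config(12, 2000))
  fitted <- rmsd_series(g, reference = ref)
  unfitted <- rmsd_series(g, reference = ref, superpose = FALSE)
  expect_true(all(fitted$value <= unfitted$value + 1e-12))
  # isotropic uncorrelated noise: raw RMSD concentrates at sigma * sqrt(3)
  expect_equal(mean(unfitted$value), 0.6 * sqrt(3), tolerance = 0.02)
  expect_equal(mean(fitted$value), mean(unfitted$value), tolerance = 0.1)
})

test_that("radius of gyration matches closed forms and brute force", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1, 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  pts <- with_seed_test(8, matrix(rnorm(150), 50, 3))
  direct <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
  expect_equal(radius_of_gyration(pts), direct, tolerance = 1e-12)
  # rigid-body invariance
  moved <- pts %*% random_rotation(2) + rep(c(10, -4, 2), each = 50)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(pts),
               tolerance = 1e-10)
  # mass weighting shifts the centroid
  m <- radius_of_gyration(two, masses = c(3, 1))
  expect_equal(m, sqrt(3 * 0.5^2 / 4 + 1.5^2 / 4))
})

test_that("RMSF is zero for static trajectories and order-invariant", {
  topo <- topology(rep("CA", 4), rep("C", 4), 1:4)
  static <- trajectory(topo, array(2, c(6, 4, 3)))
  expect_equal(rmsf(static)$rmsf, rep(0, 4))
  g <- gaussian_ensemble(matrix(rnorm(12), 4, 3), c(0.5, 1, 2, 1),
                         cfg = generator_config(2, 500))
  r1 <- rmsf(g, superpose = FALSE)
  perm <- with_seed_test(1, sample(500))
  g2 <- trajectory(g$topology, g$coords[perm, , ], g$frame_spacing_ns)
  expect_equal(rmsf(g2, superpose = FALSE)$rmsf, r1$rmsf, tolerance = 1e-12)
  expect_error(rmsf(trajectory(topo, array(0, c(1, 4, 3)))), "2 frames")
})

test_that("DCCM hits the trivial correlation limits", {
  topo <- topology(rep("CA", 3), rep("C", 3), 1:3)
  nf <- 40
  disp <- with_seed_test(5, rnorm(nf))
  coords <- array(0, c(nf, 3, 3))
  coords[, 1, 1] <- disp          # identical motion on sites 1 and 2
  coords[, 2, 1] <- disp
  coords[, 3, 1] <- -disp         # exact anti-phase on site 3
  coords[, 1, 2] <- 5; coords[, 2, 2] <- 10; coords[, 3, 2] <- 15
  tr <- trajectory(topo, coords)
  D <- dccm(tr, superpose = FALSE)
  expect_equal(D[1, 2], 1, tolerance = 1e-12)
  expect_equal(D[1, 3], -1, tolerance = 1e-12)
  expect_equal(diag(D), rep(1, 3))
})

test_that("DCCM is symmetric with unit diagonal and bounded entries", {
  ref <- with_seed_test(9, matrix(rnorm(30, sd = 10), 10, 3))
  g <- gaussian_ensemble(ref, runif(10, 0.3, 2), cfg = generator_config(3, 300))
  D <- dccm(g)
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(D >= -1 & D <= 1))
  expect_equal(diag(D), rep(1, 10))
})

test_that("zero-variance sites produce NaN DCCM entries, never zero", {
  topo <- topology(rep("CA", 2), rep("C", 2), 1:2)
  coords <- array(0, c(10, 2, 3))
  coords[, 1, 1] <- with_seed_test(2, rnorm(10))
  tr <- trajectory(topo, coords)   # site 2 never moves
  expect_warning(D <- dccm(tr, superpose = FALSE), "zero")
  expect_true(is.nan(D[1, 2]))
  expect_true(is.nan(D[2, 2]))
})

test_that("pocket distance matches brute-force centroids and is symmetric", {
  topo <- topology(rep("CA", 2), rep("C", 2), c(1L, 50L))
  coords <- array(0, c(4, 2, 3))
  coords[, 2, 1] <- 5
  tr <- trajectory(topo, coords)
  s <- pocket_distance(tr, group_a = 1, group_b = 50)
  expect_equal(s$value, rep(5, 4))
  expect_equal(pocket_distance(tr, 50, 1)$value, s$value)
  expect_error(pocket_distance(tr, 7, 50), "no C-alpha")

  set.seed(77)
  topo2 <- topology(rep("CA", 6), rep("C", 6), 1:6)
  coords2 <- array(rnorm(2 * 6 * 3), c(2, 6, 3))
  tr2 <- trajectory(topo2, coords2)
  s2 <- pocket_distance(tr2, 1:3, 4:6)
  for (f in 1:2) {
    ca <- colMeans(coords2[f, 1:3, ]); cb <- colMeans(coords2[f, 4:6, ])
    expect_equal(s2$value[f], sqrt(sum((ca - cb)^2)), tolerance = 1e-12)
  }
})
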