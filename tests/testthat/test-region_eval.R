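test_that("RGER counts asymmetric membership pairs over all pairs", {
  g <- line_geometry(2)
  # C_1 = {1,2}, C_2 = {2}: one asymmetric pair out of one
  cm <- rsedegree:::new_cluster_map(list(c(1L, 2L), 2L), "combined", 0.5, g)
  expect_equal(rger(cm), 1.0)
  # fully symmetric membership: zero errors
  sym <- rsedegree:::new_cluster_map(list(c(1L, 2L), c(1L, 2L)), "combined", 0.5, g)
  expect_equal(rger(sym), 0)
  withr::local_seed(14)
  g8 <- line_geometry(8)
  for (i in 1:10) {
    cm8 <- random_cluster_map(8, g8)
    expect_equal(rger(cm8), rger_oracle(cm8$clusters))
  }
})

test_that("cluster-size maps count members and containments consistently", {
  g <- line_geometry(3)
  # singletons
  s <- rsedegree:::new_cluster_map(list(1L, 2L, 3L), "combined", 0.5, g)
  maps <- cluster_size_maps(s)
  expect_equal(maps$type_I, rep(1, 3))
  expect_equal(maps$type_II, rep(1, 3))
  # one symmetric 3-voxel cluster shared by all seeds: M = N = 3
  all3 <- rsedegree:::new_cluster_map(rep(list(1:3), 3), "combined", 0.5, g)
  maps3 <- cluster_size_maps(all3)
  expect_equal(maps3$type_I, rep(3, 3))
  expect_equal(maps3$type_II, rep(3, 3))
  withr::local_seed(15)
  g9 <- line_geometry(9)
  for (i in 1:10) {
    cm <- random_cluster_map(9, g9)
    o <- size_maps_oracle(cm$clusters)
    m <- cluster_size_maps(cm)
    expect_equal(m$type_I, o$M)
    expect_equal(m$type_II, o$N)
    # membership double-count identity
    expect_equal(sum(m$type_I), sum(m$type_II))
    expect_true(all(m$type_I >= 1) && all(m$type_II >= 1))
  }
})

test_that("z-scoring standardizes to mean 0 and unit SD", {
  expect_equal(zscore_map(c(1, 2, 3), ddof = 1), c(-1, 0, 1))
  withr::local_seed(16)
  x <- rnorm(50, mean = 4, sd = 3)
  z <- zscore_map(x)                      # population SD default
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_error(zscore_map(rep(2, 10)), "zero variance")
})

test_that("mask-normalized smoothing preserves constants and matches the kernel oracle", {
  withr::local_seed(17)
  mask <- array(runif(6 * 6 * 4) > 0.35, c(6, 6, 4))
  mask[1, 1, 1] <- TRUE
  g <- mask_geometry(mask, voxel_size = c(3, 3, 3))
  # constant map unchanged
  expect_equal(smooth_map(rep(2.5, g$V), g, 8), rep(2.5, g$V), tolerance = 1e-12)
  # fwhm 0 is the identity
  x <- rnorm(g$V)
  expect_identical(smooth_map(x, g, 0), x)
  # delta and random maps match the direct Gaussian summation
  d <- numeric(g$V); d[round(g$V / 2)] <- 1
  expect_equal(smooth_map(d, g, 8), smooth_oracle(d, g, 8), tolerance = 1e-8)
  expect_equal(smooth_map(x, g, 8), smooth_oracle(x, g, 8), tolerance = 1e-8)
  # linearity and positivity
  y <- rnorm(g$V)
  expect_equal(smooth_map(2 * x + y, g, 8),
               2 * smooth_map(x, g, 8) + smooth_map(y, g, 8), tolerance = 1e-10)
  expect_true(all(smooth_map(abs(x), g, 8) >= 0))
  # NaN voxels are excluded from the support, not spread
  xn <- x; xn[5] <- NaN
  sm <- smooth_map(xn, g, 8)
  expect_true(is.nan(sm[5]))
  expect_true(all(is.finite(sm[-5])))
})

test_that("ICC agrees with the aov mean-squares oracle and behaves at the extremes", {
  withr::local_seed(18)
  a <- rnorm(6); b <- a + rnorm(6, sd = 0.3)
  expect_equal(icc_pair(a, b), icc_a1_aov(a, b), tolerance = 1e-10)
  # hand table, 4 subjects
  a4 <- c(9, 6, 8, 7); b4 <- c(8, 5, 9, 6)
  expect_equal(icc_pair(a4, b4), icc_a1_aov(a4, b4), tolerance = 1e-10)
  # identical measurements: ICC 1 everywhere
  A <- matrix(rnorm(5 * 7), 5, 7)
  expect_equal(map_agreement_icc(A, A), rep(1, 7), tolerance = 1e-12)
  # consistency variant is invariant to an additive rater offset
  expect_equal(icc_pair(a, b + 5, variant = "C1"),
               icc_pair(a, b, variant = "C1"), tolerance = 1e-10)
  expect_error(map_agreement_icc(A[1:2, ], A[1:2, ]), "3 subjects")
  expect_error(map_agreement_icc(A, A[, 1:3]), "shape")
})

test_that("permuted subjects give near-zero expected agreement", {
  withr::local_seed(19)
  n <- 12; V <- 400
  A <- matrix(rnorm(n * V), n, V)
  B <- A[sample(n), ] + matrix(rnorm(n * V, sd = 0.1), n, V)
  icc <- map_agreement_icc(A, B)
  expect_lt(abs(mean(icc)), 0.1)
})
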