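test_that("block phantoms have the specified structure and are seed-deterministic", {
  parcels <- list(list(origin = c(0, 0, 0), size = c(2, 2, 1)),
                  list(origin = c(2, 2, 1), size = c(2, 1, 1)))
  ph <- make_block_phantom(c(4, 4, 2), parcels, T = 50, seed = 3)
  expect_equal(lengths(ph$parcels), c(4, 2))
  # labels partition the mask; background voxels are singleton regions
  expect_equal(sort(unique(ph$labels[ph$labels <= 2])), 1:2)
  bg <- ph$labels[-unlist(ph$parcels)]
  expect_equal(length(bg), length(unique(bg)))
  ph2 <- make_block_phantom(c(4, 4, 2), parcels, T = 50, seed = 3)
  expect_identical(ph$series$data, ph2$series$data)
  ph3 <- make_block_phantom(c(4, 4, 2), parcels, T = 50, seed = 4)
  expect_false(identical(ph$series$data, ph3$series$data))
  expect_error(make_block_phantom(c(4, 4, 2),
    list(list(origin = c(0, 0, 0), size = c(2, 2, 1)),
         list(origin = c(1, 1, 0), size = c(2, 2, 1)))), "overlap")
  expect_error(make_block_phantom(c(4, 4, 2),
    list(list(origin = c(3, 3, 1), size = c(2, 2, 1)))), "grid")
})

test_that("phantom correlations follow the variance-share closed forms", {
  parcels <- list(list(origin = c(0, 0, 0), size = c(3, 3, 1)),
                  list(origin = c(0, 0, 2), size = c(3, 3, 1)))
  # noiseless limit: within-parcel r = 1
  ph0 <- make_block_phantom(c(3, 3, 3), parcels, T = 40,
                            within_share = 1, between_share = 0, noise_sd = 0,
                            seed = 5)
  tc0 <- temporal_correlation_matrix(ph0$series)
  p1 <- ph0$parcels[[1]]
  expect_equal(tc0$values[p1, p1], matrix(1, 9, 9), tolerance = 1e-12)
  # long-series check of the closed forms at stated shares
  w <- 0.6; b <- 0.2; nsd <- sqrt(0.2)
  ph <- make_block_phantom(c(3, 3, 3), parcels, links = list(c(1, 2)),
                           T = 10000, within_share = w, between_share = b,
                           noise_sd = nsd, seed = 6)
  tc <- temporal_correlation_matrix(ph$series)
  a <- ph$parcels[[1]]; bb <- ph$parcels[[2]]
  tot <- w + b + nsd^2
  within <- tc$values[a, a][upper.tri(matrix(0, 9, 9))]
  expect_lt(abs(mean(within) - (w + b) / tot), 0.03)
  expect_lt(abs(mean(tc$values[a, bb]) - b / tot), 0.03)
  # unlinked parcels: expected r = 0
  ph_nl <- make_block_phantom(c(3, 3, 3), parcels, links = list(), T = 10000,
                              within_share = w, between_share = 0,
                              noise_sd = nsd, seed = 7)
  tc_nl <- temporal_correlation_matrix(ph_nl$series)
  expect_lt(abs(mean(tc_nl$values[a, bb])), 0.03)
})

test_that("the toy network encodes the two-large/two-small topology", {
  toy <- figure1_toy()
  expect_equal(dim(toy$adjacency), c(6, 6))
  expect_equal(toy$adjacency, t(toy$adjacency))
  expect_equal(toy$partition, c(1L, 1L, 2L, 2L, 3L, 4L))
  # within-region pairs, full A-B cross-connections, C-D, nothing else
  expect_equal(sum(toy$adjacency) / 2, 7)
  expect_equal(toy$adjacency[1, 2], 1)
  expect_equal(toy$adjacency[3, 4], 1)
  expect_equal(toy$adjacency[5, 6], 1)
  expect_true(all(toy$adjacency[1:2, 3:4] == 1))
  expect_true(all(toy$adjacency[1:4, 5:6] == 0))
  expect_equal(toy$matrix$values[1, 2], 0.9)
  expect_equal(diag(toy$matrix$values), rep(1, 6))
  # ground-truth clusters are the regions
  expect_equal(toy$clusters$clusters[[1]], c(1L, 2L))
  expect_equal(toy$clusters$clusters[[5]], 5L)
})

test_that("multi-subject generation separates subject and scan variability", {
  parcels <- list(list(origin = c(0, 0, 0), size = c(2, 2, 1)),
                  list(origin = c(3, 0, 0), size = c(2, 2, 1)))
  # no scan noise and no jitter: scans identical within subject
  ms0 <- make_multisubject(c(6, 3, 1), parcels, list(c(1, 2)),
                           n_subjects = 2, n_scans = 3, T = 20,
                           scan_noise_sd = 0, size_jitter = 0, seed = 8)
  expect_equal(ms0[[1]][[1]]$series$data, ms0[[1]][[2]]$series$data,
               tolerance = 1e-12)
  expect_false(identical(ms0[[1]][[1]]$series$data, ms0[[2]][[1]]$series$data))
  # determinism under the master seed
  ms0b <- make_multisubject(c(6, 3, 1), parcels, list(c(1, 2)),
                            n_subjects = 2, n_scans = 3, T = 20,
                            scan_noise_sd = 0, size_jitter = 0, seed = 8)
  expect_identical(ms0[[2]][[3]]$series$data, ms0b[[2]][[3]]$series$data)
  # size jitter changes parcel extents between scans
  ms1 <- make_multisubject(c(6, 3, 1), parcels, list(c(1, 2)),
                           n_subjects = 1, n_scans = 6, T = 5,
                           size_jitter = 1, seed = 9)
  sizes <- vapply(ms1[[1]], function(p) length(p$parcels[[1]]), numeric(1))
  expect_gt(length(unique(sizes)), 1)
  expect_error(make_multisubject(c(6, 3, 1), parcels, list(), 2, n_scans = 2),
               "n_scans")
})
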