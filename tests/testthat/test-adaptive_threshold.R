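make_cm <- function(R, geometry, flavor = "temporal")
  rsedegree:::new_correlation_matrix(R, flavor, geometry)

test_that("two-step neighbour filtering follows the enumeration oracle", {
  # 4-voxel line: voxel 2 has face neighbours 1 and 3
  g <- line_geometry(4)
  R <- diag(4)
  set_r <- function(i, j, v) { R[i, j] <<- v; R[j, i] <<- v }
  set_r(1, 2, 0.4); set_r(2, 3, 0.8); set_r(3, 4, 0.5)
  m <- make_cm(R, g)
  # voxel 2 neighbours {0.4, 0.8}, mean_pos given: step 1 keeps both,
  # step 2 mean 0.6 discards 0.4 -> 0.8
  expect_equal(voxel_threshold(m, 2, g, mean_pos = 0.3), 0.8)
  # all neighbours filtered at step 1 -> NaN
  expect_true(is.nan(voxel_threshold(m, 1, g, mean_pos = 0.5)))
  # constant survivors: threshold equals the constant
  Rc <- diag(4); Rc[1, 2] <- Rc[2, 1] <- 0.6
  Rc[2, 3] <- Rc[3, 2] <- 0.6; Rc[3, 4] <- Rc[4, 3] <- 0.6
  expect_equal(voxel_threshold(make_cm(Rc, g), 2, g, mean_pos = 0.3), 0.6)
})

test_that("the worked three-neighbour example gives 0.8", {
  # neighbours {0.4, 0.5, 0.8} with mean_pos 0.3: step-1 survivors all,
  # mean 0.5667, step-2 survivor {0.8}
  g <- mask_geometry(array(TRUE, c(3, 3, 1)))
  centre <- g$vox_index[2, 2, 1]
  nbr <- neighbor_list(g, 6L)[[centre]]
  expect_length(nbr, 4)
  R <- diag(g$V)
  vals <- c(0.4, 0.5, 0.8, -0.2)
  for (k in seq_along(nbr)) { R[centre, nbr[k]] <- vals[k]; R[nbr[k], centre] <- vals[k] }
  got <- voxel_threshold(make_cm(R, g), centre, g, mean_pos = 0.3)
  expect_equal(got, 0.8)
  expect_equal(got, voxel_threshold_oracle(R, centre, neighbor_list(g, 6L), 0.3))
})

test_that("T_a averages defined per-voxel thresholds and matches the naive oracle", {
  # homogeneous: every neighbour pair at r = 0.7 -> T_a = 0.7 exactly
  g <- mask_geometry(array(TRUE, c(4, 4, 4)))
  R <- matrix(0.7, g$V, g$V); diag(R) <- 1
  rep_h <- adaptive_threshold(make_cm(R, g))
  expect_identical(rep_h$T_a, 0.7)
  expect_identical(rep_h$n_excluded_voxels, 0L)
  # two-voxel mask: threshold is the single neighbour correlation
  g2 <- line_geometry(2)
  R2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(adaptive_threshold(make_cm(R2, g2))$T_a, 0.9)
  # random phantom: agreement with the naive reimplementation to 1e-12
  ph <- make_block_phantom(c(5, 5, 3),
                           list(list(origin = c(0, 0, 0), size = c(3, 3, 2))),
                           T = 80, seed = 17)
  tc <- temporal_correlation_matrix(ph$series)
  rep_p <- adaptive_threshold(tc)
  expect_equal(rep_p$T_a, adaptive_threshold_oracle(tc$values, ph$series$geometry),
               tolerance = 1e-12)
  # invariants: defined thresholds never sit below mean_pos; T_a is their mean
  thr <- rep_p$per_voxel_thresholds
  expect_true(all(thr[!is.nan(thr)] >= rep_p$mean_pos))
  expect_equal(rep_p$T_a, mean(thr[!is.nan(thr)]))
})

test_that("second filtering never lowers a per-voxel threshold", {
  withr::local_seed(8)
  g <- mask_geometry(array(TRUE, c(4, 4, 2)))
  nbrs6 <- neighbor_list(g, 6L)
  for (rep_i in 1:20) {
    R <- random_corr_matrix(g$V)
    m <- make_cm(R, g)
    mp <- mean_positive_correlation(m)
    v <- sample(g$V, 1)
    thr <- voxel_threshold(m, v, g, mp)
    r <- R[v, nbrs6[[v]]]
    surv1 <- r[r >= 0 & r >= mp]
    if (!is.nan(thr)) expect_gte(thr, mean(surv1))
  }
})

test_that("T_a is invariant to voxel ordering", {
  withr::local_seed(12)
  ph <- make_block_phantom(c(4, 4, 2),
                           list(list(origin = c(0, 0, 0), size = c(2, 2, 2))),
                           T = 60, seed = 4)
  tc <- temporal_correlation_matrix(ph$series)
  g <- ph$series$geometry
  t1 <- adaptive_threshold(tc)$T_a
  # relabel voxels by permuting the grid axes (an order-consistent relabeling)
  perm_mask <- aperm(array(TRUE, g$dim), c(2, 1, 3))
  g2 <- mask_geometry(perm_mask, voxel_size = g$voxel_size[c(2, 1, 3)])
  old_lin <- g$vox_index[cbind(g2$coords[, 2], g2$coords[, 1], g2$coords[, 3]) + 1L]
  R2 <- tc$values[old_lin, old_lin]
  t2 <- adaptive_threshold(make_cm(R2, g2))$T_a
  expect_equal(t1, t2, tolerance = 1e-12)
  expect_error(adaptive_threshold(make_cm(matrix(c(1, -0.2, -0.2, 1), 2),
                                          line_geometry(2))), "no positive")
})
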