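#' Synthetic phantoms with known functional regions
#'
#' The generators emulate masked 4D BOLD data whose mask contains a few
#' block-shaped functional regions — sets of spatially adjacent voxels
#' sharing a common latent signal — embedded in background voxels that carry
#' pure noise (each background voxel is its own singleton region). Voxel
#' series are variance-share mixtures
#' `x_v = sqrt(within) s_p + sqrt(between)/sqrt(k_p) sum(s_link) + noise_sd e_v`
#' with i.i.d. standard Gaussian latent signals, so the expected
#' within-region correlation is `within / (within + between + noise_sd^2)`
#' (plus the link share for voxels of the same region, which also share the
#' link signals: `(within + between) / total`), and the correlation between
#' voxels of two linked regions is `between / (sqrt(k_p k_q) total)` where
#' `k` counts each region's links. Signals are Gaussian white noise (no
#' hemodynamic model): the method under test consumes generic correlated
#' series.
#'
#' @name phantoms
NULL

block_voxels <- function(origin, size, dims) {
  xs <- origin[1] + seq_len(size[1]) - 1L
  ys <- origin[2] + seq_len(size[2]) - 1L
  zs <- origin[3] + seq_len(size[3]) - 1L
  if (max(xs) >= dims[1] || max(ys) >= dims[2] || max(zs) >= dims[3] ||
      min(origin) < 0)
    stop("input error: parcel block exceeds the grid", call. = FALSE)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  g[, 1] + dims[1] * g[, 2] + dims[1] * dims[2] * g[, 3] + 1L  # linear index
}

#' Block phantom generator
#'
#' @param grid 3D grid dimensions; the whole grid is the mask.
#' @param parcels list of blocks, each `list(origin = c(x, y, z), size =
#'   c(dx, dy, dz))` with 0-based origins; blocks must not overlap.
#' @param links list of integer pairs: parcel indices sharing a
#'   between-region signal.
#' @param T number of time points.
#' @param within_share variance share of the region signal.
#' @param between_share variance share of the (summed, renormalized) link
#'   signals; a scalar, or one value per link.
#' @param noise_sd SD of the i.i.d. voxel noise.
#' @param seed RNG seed; identical seed and parameters give a
#'   bitwise-identical phantom.
#' @param voxel_size physical voxel edge lengths (mm).
#' @param signals optional externally drawn latent signals, a list with
#'   `s_region` (parcels x T) and `s_link` (links x T); used by
#'   [make_multisubject()] to hold signals fixed across scans of a subject.
#' @return A `phantom`: list with `series` (a [bold_series()]), `labels`
#'   (ground-truth region id per voxel; background voxels get unique
#'   singleton ids), `parcels`, `links` and `params`.
#' @export
make_block_phantom <- function(grid, parcels, links = list(), T = 300,
                               within_share = 0.8, between_share = 0.1,
                               noise_sd = sqrt(0.1), seed = 1,
                               voxel_size = c(3, 3, 3), signals = NULL) {
  stopifnot(within_share >= 0, all(between_share >= 0), noise_sd >= 0)
  if (length(links) > 0)
    between_share <- rep_len(between_share, length(links))
  set.seed(seed)
  dims <- as.integer(grid)
  nvox <- prod(dims)
  members <- lapply(parcels, function(p) block_voxels(p$origin, p$size, dims))
  if (length(members) && anyDuplicated(unlist(members)))
    stop("input error: parcel blocks overlap", call. = FALSE)
  labels <- integer(nvox)
  for (k in seq_along(members)) labels[members[[k]]] <- k
  bg <- which(labels == 0L)
  labels[bg] <- length(members) + seq_along(bg)   # singleton background regions
  # latent signals
  s_region <- if (is.null(signals))
    matrix(stats::rnorm(length(members) * T), ncol = T)
  else signals$s_region
  s_link <- if (is.null(signals))
    matrix(stats::rnorm(length(links) * T), ncol = T)
  else signals$s_link
  stopifnot(nrow(s_region) == length(members) || length(members) == 0,
            nrow(s_link) == length(links) || length(links) == 0)
  k_links <- vapply(seq_along(members), function(p) {
    sum(vapply(links, function(l) p %in% l, logical(1)))
  }, numeric(1))
  X <- matrix(stats::rnorm(nvox * T, sd = noise_sd), nrow = nvox)
  for (p in seq_along(members)) {
    sig <- sqrt(within_share) * s_region[p, ]
    if (k_links[p] > 0) {
      ls <- which(vapply(links, function(l) p %in% l, logical(1)))
      lsum <- colSums(sqrt(between_share[ls]) * s_link[ls, , drop = FALSE])
      sig <- sig + lsum / sqrt(k_links[p])
    }
    X[members[[p]], ] <- sweep(X[members[[p]], , drop = FALSE], 2L, sig, `+`)
  }
  geometry <- mask_geometry(array(TRUE, dims), voxel_size = voxel_size)
  structure(
    list(series = bold_series(X, geometry),
         labels = labels,
         parcels = members,
         links = links,
         params = list(T = T, within_share = within_share,
                       between_share = between_share, noise_sd = noise_sd,
                       seed = seed)),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  np <- length(x$parcels)
  cat(sprintf("<phantom> %d parcels (sizes %s) + %d background voxels, T=%d\n",
              np, paste(lengths(x$parcels), collapse = "/"),
              x$series$geometry$V - length(unlist(x$parcels)), x$params$T))
  invisible(x)
}

#' The six-node toy network
#'
#' Two connected large regions of two voxels each (A, B) and two connected
#' small regions of one voxel each (C, D): within-region pairs and the
#' A-B and C-D region pairs are connected (r = 0.9), nothing else. At the
#' region level every region has degree one — there is no hub — yet the
#' traditional voxel-wise degree of large-region voxels is three versus one
#' for small-region voxels, the disparity the corrected metrics remove.
#' Encoded as a correlation matrix (0.9 / 0) with a 6x1x1 geometry and the
#' ground-truth cluster map, so the same degree code paths apply unmodified.
#'
#' @return list with `adjacency` (6 x 6 0/1 matrix), `partition` (region id
#'   per voxel: A, A, B, B, C, D), `matrix` (a `correlation_matrix`),
#'   `clusters` (ground-truth `cluster_map`), `T_d` (0.5) and `r_edge`
#'   (0.9).
#' @export
figure1_toy <- function() {
  partition <- c(1L, 1L, 2L, 2L, 3L, 4L)
  adj <- matrix(0, 6, 6)
  edge <- function(i, j) { adj[i, j] <<- 1; adj[j, i] <<- 1 }
  edge(1, 2); edge(3, 4)                    # within large regions
  edge(1, 3); edge(1, 4); edge(2, 3); edge(2, 4)  # A-B fully cross-connected
  edge(5, 6)                                # C-D
  r_edge <- 0.9
  R <- adj * r_edge
  diag(R) <- 1
  geometry <- mask_geometry(array(TRUE, c(6, 1, 1)))
  clusters <- lapply(seq_len(6), function(i) which(partition == partition[i]))
  list(adjacency = adj,
       partition = partition,
       matrix = new_correlation_matrix(R, "combined", geometry),
       clusters = new_cluster_map(clusters, "combined", NA_real_, geometry),
       T_d = 0.5,
       r_edge = r_edge)
}

#' Multi-subject, multi-scan phantom series
#'
#' Emulates a test-retest design: subject-level parameters are drawn once
#' per subject (which candidate region pairs are linked, and a subject link
#' strength multiplied by `1 + between_subject_sd * z`), while scan-level
#' variation is fresh per scan — both the voxel noise (`scan_noise_sd`) and,
#' optionally, a jitter of the region extents (`size_jitter` layers added or
#' removed along the x axis per parcel and scan). With size jitter on, the
#' sizes of the regions fluctuate between scans while the subject's
#' region-level connectivity stays fixed, making region-size variance the
#' dominant scan-to-scan noise source.
#'
#' @param grid,parcels,T,within_share,between_share,voxel_size as in
#'   [make_block_phantom()].
#' @param candidate_links region pairs that MAY be linked; each is linked
#'   per subject with probability `link_prob`.
#' @param n_subjects,n_scans design size (`n_scans >= 3` for test-retest).
#' @param between_subject_sd SD of the subject effect on link strength.
#' @param scan_noise_sd voxel noise SD, fresh per scan.
#' @param size_jitter max layers added/removed from each parcel per scan
#'   (0 disables).
#' @param link_prob per-subject probability that a candidate link is on.
#' @param seed master seed; all subject and scan draws derive from it.
#' @return list of `n_subjects` lists of `n_scans` `phantom`s, with
#'   attribute `base_labels` (ground-truth labels of the unjittered layout).
#' @export
make_multisubject <- function(grid, parcels, candidate_links, n_subjects,
                              n_scans = 3, T = 150, within_share = 0.8,
                              between_share = 0.1,
                              between_subject_sd = 0.25,
                              scan_noise_sd = sqrt(0.1),
                              size_jitter = 1, link_prob = 0.5,
                              seed = 1, voxel_size = c(3, 3, 3)) {
  stopifnot(n_scans >= 3)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max, n_subjects)
  out <- lapply(seq_len(n_subjects), function(s) {
    set.seed(subject_seeds[s])
    on_links <- candidate_links[stats::runif(length(candidate_links)) < link_prob]
    # per-link graded strength: an independent subject trait for every link
    strength <- between_share *
      pmax(0.1, 1 + between_subject_sd * stats::rnorm(length(on_links)))
    # subject-level latent signals: fixed across the subject's scans
    signals <- list(
      s_region = matrix(stats::rnorm(length(parcels) * T), ncol = T),
      s_link = matrix(stats::rnorm(length(on_links) * T), ncol = T))
    scan_seeds <- sample.int(.Machine$integer.max, n_scans)
    lapply(seq_len(n_scans), function(sc) {
      set.seed(scan_seeds[sc])
      jit <- if (size_jitter > 0)
        sample(seq(-size_jitter, size_jitter), length(parcels), replace = TRUE)
      else rep(0L, length(parcels))
      pj <- Map(function(p, j) {
        sz <- p$size
        sz[1] <- max(1L, sz[1] + j)
        list(origin = p$origin, size = sz)
      }, parcels, jit)
      make_block_phantom(grid, pj, links = on_links, T = T,
                         within_share = within_share,
                         between_share = strength,
                         noise_sd = scan_noise_sd,
                         seed = sample.int(.Machine$integer.max, 1),
                         voxel_size = voxel_size, signals = signals)
    })
  })
  base <- make_block_phantom(grid, parcels, links = candidate_links, T = 3,
                             seed = 0, voxel_size = voxel_size)
  attr(out, "base_labels") <- base$labels
  out
}
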