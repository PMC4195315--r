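#' Data-driven region-growing threshold
#'
#' The region-growing stop threshold `T_a` is estimated from the correlations
#' between each voxel and its six face neighbours, under the assumption that
#' nearest neighbours are the voxels most likely to share a functional
#' region. Two filtering steps per voxel: (1) neighbours with negative
#' correlation, or correlation below the mean positive correlation of the
#' whole matrix, are excluded; (2) the survivors are averaged and any
#' survivor strictly below that average is discarded. The voxel's threshold
#' is the mean of the final survivors; `T_a` is the average of these
#' per-voxel thresholds over all voxels that have one.
#'
#' @name adaptive_threshold_doc
NULL

#' Per-voxel threshold by two-step neighbour filtering
#'
#' @param matrix a `correlation_matrix`.
#' @param voxel voxel number in `1..V`.
#' @param geometry the [mask_geometry()] (defaults to the matrix's own).
#' @param mean_pos the mean positive off-diagonal correlation of `matrix`
#'   (see [mean_positive_correlation()]).
#' @param nbrs6 optional precomputed [neighbor_list()] with connectivity 6.
#' @return scalar threshold, or `NaN` when no neighbour survives the first
#'   filtering (a valid outcome, reported as excluded).
#' @export
voxel_threshold <- function(matrix, voxel, geometry = matrix$geometry,
                            mean_pos = mean_positive_correlation(matrix),
                            nbrs6 = NULL) {
  nb <- if (is.null(nbrs6)) neighbor_list(geometry, 6L)[[voxel]] else nbrs6[[voxel]]
  if (length(nb) == 0L) return(NaN)
  r <- matrix$values[voxel, nb]
  keep <- r >= 0 & r >= mean_pos          # first filtering; ties survive
  r <- r[keep]
  if (length(r) == 0L) return(NaN)
  m <- mean(r)
  r <- r[r >= m]                          # second filtering: strictly lower dropped
  mean(r)
}

#' Adaptive threshold for region growing
#'
#' @param matrix a `correlation_matrix` (temporal or spatial).
#' @param geometry the [mask_geometry()] (defaults to the matrix's own).
#' @return A `threshold_report`: list with `T_a`, `per_voxel_thresholds`
#'   (`NaN` where undefined), `n_excluded_voxels`, `mean_pos`, `flavor`.
#' @export
adaptive_threshold <- function(matrix, geometry = matrix$geometry) {
  mean_pos <- mean_positive_correlation(matrix)
  nbrs6 <- neighbor_list(geometry, 6L)
  thr <- vapply(seq_len(geometry$V), function(i) {
    voxel_threshold(matrix, i, geometry, mean_pos, nbrs6)
  }, numeric(1))
  defined <- !is.nan(thr)
  if (!any(defined))
    stop("value error: no voxel has an estimable threshold", call. = FALSE)
  structure(
    list(T_a = mean(thr[defined]),
         per_voxel_thresholds = thr,
         n_excluded_voxels = sum(!defined),
         mean_pos = mean_pos,
         flavor = matrix$flavor),
    class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("<threshold_report> %s flavor: T_a = %.4f (%d voxels excluded)\n",
              x$flavor, x$T_a, x$n_excluded_voxels))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.threshold_report <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$per_voxel_thresholds),
                 threshold = x$per_voxel_thresholds,
                 defined = !is.nan(x$per_voxel_thresholds))
}

#' @rdname glance
#' @export
glance.threshold_report <- function(x, ...) {
  tibble::tibble(T_a = x$T_a, flavor = x$flavor, mean_pos = x$mean_pos,
                 n_excluded_voxels = x$n_excluded_voxels,
                 n_voxels = length(x$per_voxel_thresholds))
}
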