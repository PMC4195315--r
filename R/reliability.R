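#' Test-retest reliability of degree maps
#'
#' Long-term test-retest reliability is measured voxel-wise as the ICC
#' between the first scan and the average of the two later scans, across
#' subjects. Maps are expected to be z-scored and then smoothed before this
#' step (that order is part of the evaluation contract; see
#' [prepare_maps()]).
#'
#' @param scan1_maps,scan2_maps,scan3_maps numeric matrices, subjects x
#'   voxels, one per scan (equal shapes, >= 3 subjects).
#' @param variant ICC variant, see [icc_pair()].
#' @param metric,corrected,T_d optional provenance recorded in the result.
#' @return A `reliability_result`: list with `icc_map` (per-voxel ICC,
#'   `NaN` where undefined), `metric`, `corrected`, `T_d`, `n_subjects`.
#' @export
test_retest_icc <- function(scan1_maps, scan2_maps, scan3_maps,
                            variant = c("A1", "C1"),
                            metric = NA_character_, corrected = NA,
                            T_d = NA_real_) {
  variant <- match.arg(variant)
  scan1_maps <- as.matrix(scan1_maps)
  scan2_maps <- as.matrix(scan2_maps)
  scan3_maps <- as.matrix(scan3_maps)
  if (!all(dim(scan1_maps) == dim(scan2_maps)) ||
      !all(dim(scan1_maps) == dim(scan3_maps)))
    stop("input error: scan map sets differ in shape", call. = FALSE)
  retest <- (scan2_maps + scan3_maps) / 2
  icc <- map_agreement_icc(scan1_maps, retest, variant)
  structure(list(icc_map = icc, metric = metric, corrected = corrected,
                 T_d = T_d, n_subjects = nrow(scan1_maps),
                 variant = variant),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %s%s T_d=%s: mean ICC %.3f over %d voxels (%d subjects)\n",
              x$metric, if (isTRUE(x$corrected)) "_RSE" else "",
              format(x$T_d), mean(x$icc_map, na.rm = TRUE),
              length(x$icc_map), x$n_subjects))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.reliability_result <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$icc_map), metric = x$metric,
                 T_d = x$T_d, corrected = x$corrected, icc = x$icc_map)
}

#' @rdname glance
#' @export
glance.reliability_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, T_d = x$T_d, corrected = x$corrected,
                 n_subjects = x$n_subjects,
                 mean_icc = mean(x$icc_map, na.rm = TRUE),
                 n_undefined = sum(is.nan(x$icc_map)))
}

#' Z-score then smooth a set of per-subject maps
#'
#' The standardize-then-smooth order applied to every map before ICC
#' computation.
#'
#' @param maps subjects x voxels matrix.
#' @param geometry a [mask_geometry()].
#' @param fwhm_mm smoothing kernel FWHM in mm (default 8).
#' @param ddof z-score denominator choice, see [zscore_map()].
#' @return matrix of the same shape.
#' @export
prepare_maps <- function(maps, geometry, fwhm_mm = 8, ddof = 0) {
  maps <- as.matrix(maps)
  t(apply(maps, 1L, function(v) {
    # a flat map carries no spatial information: center it instead of failing
    z <- if (stats::sd(v) == 0) v - mean(v) else zscore_map(v, ddof)
    smooth_map(z, geometry, fwhm_mm)
  }))
}

#' Reliability across metrics, corrections and thresholds
#'
#' Takes per-scan degree sweeps (tibbles from [threshold_sweep()], one list
#' element per subject within each scan list), z-scores and smooths each
#' subject map, and tabulates the mask-mean test-retest ICC per
#' (metric, corrected, T_d) cell, flagging the optimal threshold per
#' metric/correction.
#'
#' @param scan_sweeps list of three lists (scan 1, 2, 3), each a list of
#'   per-subject `degree_sweep` tibbles over identical grids.
#' @param geometry a [mask_geometry()].
#' @param fwhm_mm smoothing FWHM in mm.
#' @param variant ICC variant.
#' @return A tibble (class `reliability_sweep`) with columns `metric`,
#'   `corrected`, `T_d`, `mean_icc`, `optimal`.
#' @export
reliability_sweep <- function(scan_sweeps, geometry, fwhm_mm = 8,
                              variant = c("A1", "C1")) {
  variant <- match.arg(variant)
  stopifnot(length(scan_sweeps) == 3L)
  n_sub <- length(scan_sweeps[[1]])
  stopifnot(length(scan_sweeps[[2]]) == n_sub, length(scan_sweeps[[3]]) == n_sub)
  cells <- dplyr::distinct(scan_sweeps[[1]][[1]],
                           .data$metric, .data$T_d, .data$corrected)
  rows <- purrr::pmap(cells, function(metric, T_d, corrected) {
    get_maps <- function(scan) {
      m <- t(vapply(scan_sweeps[[scan]], function(sw) {
        sel <- sw$metric == metric & sw$T_d == T_d & sw$corrected == corrected
        sw$value[sel]
      }, numeric(geometry$V)))
      prepare_maps(m, geometry, fwhm_mm)
    }
    res <- test_retest_icc(get_maps(1), get_maps(2), get_maps(3),
                           variant, metric, corrected, T_d)
    glance(res)[, c("metric", "T_d", "corrected", "mean_icc")]
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$metric, .data$corrected),
    optimal = .data$mean_icc == max(.data$mean_icc))
  out <- dplyr::ungroup(out)
  class(out) <- c("reliability_sweep", class(out))
  out
}
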