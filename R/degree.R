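#' Degree metrics and their region-size corrections
#'
#' In a voxel-wise network, two voxels count as connected when their
#' correlation reaches the connectivity threshold `T_d`. Four weightings are
#' supported: unweighted (`U`, weight 1), weighted (`W`, weight r),
#' squared-weight (`WS`, weight r^2, the "intrinsic connectivity contrast")
#' and Fisher-z weighted (`WF`, weight atanh(r)). A voxel's traditional
#' degree scales both with the size of the functional region it sits in
#' (self-connections) and with the sizes of the regions it connects to. The
#' corrected (RSE, reduce-size-effect) metrics remove both terms: the `g`
#' factor drops connections to voxels of the voxel's own grown cluster, and
#' each remaining connection to voxel j is divided by `s(i, j)`, the number
#' of voxels of `C_j` outside `C_i` that are themselves connected to i — the
#' effective size of the region being connected to.
#'
#' @name degree_metrics
NULL

METRICS <- c("U", "W", "WS", "WF")

#' Connection indicator
#'
#' @param r correlation value(s).
#' @param T_d connectivity threshold.
#' @return 1 where `r >= T_d` (inclusive), else 0.
#' @export
indicator <- function(r, T_d) as.numeric(r >= T_d)

#' Connection weight under a degree metric
#'
#' @param r correlation value(s).
#' @param metric one of "U", "W", "WS", "WF".
#' @return weights: 1, r, r^2, or atanh(r) respectively.
#' @export
weight <- function(r, metric = METRICS) {
  metric <- match.arg(metric)
  if (metric == "WF" && any(abs(r) >= 1))
    stop("value error: |r| = 1 gives an infinite Fisher-z weight", call. = FALSE)
  switch(metric,
         U = rep(1, length(r)),
         W = r,
         WS = r^2,
         WF = atanh(r))
}

new_degree_result <- function(values, metric, T_d, corrected,
                              cluster_map_id = NULL) {
  structure(list(values = values, metric = metric, T_d = T_d,
                 corrected = corrected, cluster_map_id = cluster_map_id),
            class = "degree_result")
}

#' @export
print.degree_result <- function(x, ...) {
  cat(sprintf("<degree_result> %s%s at T_d = %.2f: %d voxels, mean %.3f\n",
              x$metric, if (x$corrected) "_RSE" else "", x$T_d,
              length(x$values), mean(x$values)))
  invisible(x)
}

# weight * indicator matrix with the self-term removed
wf_matrix <- function(R, metric, T_d) {
  f <- R >= T_d
  diag(f) <- FALSE
  if (metric == "WF" && any(abs(R[f]) >= 1))
    stop("value error: |r| = 1 among connected pairs gives an infinite Fisher-z weight",
         call. = FALSE)
  w <- switch(metric, U = (R * 0) + 1, W = R, WS = R^2, WF = atanh(R * (abs(R) < 1)))
  w * f
}

#' Traditional voxel-wise degree
#'
#' `values[i] = sum_{j != i} weight(r(i,j)) * [r(i,j) >= T_d]`. The self-term
#' is excluded: r(i,i) = 1 would add the same constant to every voxel.
#'
#' @param matrix a `correlation_matrix`.
#' @param T_d connectivity threshold in (0, 1); the conventional sweep range
#'   is 0.15-0.5.
#' @param metric one of "U", "W", "WS", "WF".
#' @param include_self count the self-term j = i as well (strict-formula
#'   mode; default `FALSE`).
#' @return A `degree_result` with per-voxel `values`.
#' @export
traditional_degree <- function(matrix, T_d, metric = METRICS,
                               include_self = FALSE) {
  metric <- match.arg(metric)
  stopifnot(T_d > 0, T_d < 1)
  R <- matrix$values
  vals <- rowSums(wf_matrix(R, metric, T_d))
  if (include_self) {
    d <- diag(R)
    if (metric == "WF" && any(abs(d[d >= T_d]) >= 1))
      stop("value error: self-correlation 1 with WF", call. = FALSE)
    vals <- vals + weight(d, metric) * indicator(d, T_d)
  }
  new_degree_result(vals, metric, T_d, corrected = FALSE)
}

#' Region-size corrected voxel-wise degree
#'
#' `values[i] = sum_j weight(r(i,j)) * f(i,j) * g(i,j) / s(i,j)` with
#' `g(i,j) = 0` when j belongs to the cluster `C_i` grown from i (self-
#' connections within the region are disregarded) and
#' `s(i,j) = |{k in C_j \ C_i : r(i,k) >= T_d}|` (the connection is divided
#' by the effective size of j's region; shared members and members not
#' connected to i are ignored so the size is not overestimated). Whenever a
#' term survives `f * g = 1`, j itself lies in `C_j \ C_i` and is connected
#' to i, so `s >= 1` and no division by zero can occur.
#'
#' @inheritParams traditional_degree
#' @param clusters a `cluster_map` (normally the combined one).
#' @return A `degree_result` with `corrected = TRUE`.
#' @export
rse_degree <- function(matrix, T_d, clusters, metric = METRICS) {
  metric <- match.arg(metric)
  stopifnot(T_d > 0, T_d < 1)
  R <- matrix$values
  V <- nrow(R)
  if (length(clusters$clusters) != V)
    stop("input error: cluster map does not match matrix size", call. = FALSE)
  W <- wf_matrix(R, metric, T_d)
  f <- R >= T_d
  diag(f) <- FALSE
  vals <- numeric(V)
  for (i in seq_len(V)) {
    in_Ci <- logical(V)
    in_Ci[clusters$clusters[[i]]] <- TRUE
    js <- which(f[i, ] & !in_Ci)          # f(i,j) = 1 and g(i,j) = 1
    if (length(js) == 0L) next
    fi <- f[i, ]
    s <- vapply(js, function(j) {
      Cj <- clusters$clusters[[j]]
      sum(fi[Cj] & !in_Ci[Cj])
    }, numeric(1))
    stopifnot(all(s >= 1))                # guaranteed: j itself qualifies
    vals[i] <- sum(W[i, js] / s)
  }
  new_degree_result(vals, metric, T_d, corrected = TRUE,
                    cluster_map_id = clusters$flavor)
}

#' Degree metrics across a grid of connectivity thresholds
#'
#' Computes all four traditional and all four corrected metrics at each
#' threshold of the grid (default 0.15 to 0.50 in steps of 0.05).
#'
#' @param matrix a `correlation_matrix`.
#' @param clusters a `cluster_map` for the corrected metrics.
#' @param grid numeric vector of thresholds in (0, 1).
#' @param metrics subset of `c("U", "W", "WS", "WF")`.
#' @param corrected logical vector: compute traditional (`FALSE`),
#'   corrected (`TRUE`), or both (default).
#' @return A tibble with columns `voxel`, `metric`, `T_d`, `corrected`,
#'   `value` (class `degree_sweep`).
#' @export
threshold_sweep <- function(matrix, clusters, grid = default_td_grid(),
                            metrics = METRICS, corrected = c(FALSE, TRUE)) {
  stopifnot(length(grid) > 0, all(grid > 0 & grid < 1))
  rows <- purrr::map(grid, function(td) {
    purrr::map(metrics, function(m) {
      purrr::map(corrected, function(cc) {
        res <- if (cc) rse_degree(matrix, td, clusters, m)
               else traditional_degree(matrix, td, m)
        tidy(res)
      })
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(purrr::flatten(rows)))
  class(out) <- c("degree_sweep", class(out))
  out
}

#' Default connectivity-threshold grid
#'
#' 0.15 to 0.50 in steps of 0.05 (8 values).
#' @return numeric vector.
#' @export
default_td_grid <- function() seq(0.15, 0.50, by = 0.05)

#' @rdname tidy
#' @export
tidy.degree_result <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$values),
                 metric = x$metric, T_d = x$T_d, corrected = x$corrected,
                 value = x$values)
}

#' @rdname glance
#' @export
glance.degree_result <- function(x, ...) {
  tibble::tibble(metric = x$metric, T_d = x$T_d, corrected = x$corrected,
                 n_voxels = length(x$values),
                 mean = mean(x$values), sd = stats::sd(x$values),
                 max = max(x$values))
}
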