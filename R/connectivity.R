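#' Voxel-by-voxel correlation matrices
#'
#' Functional connectivity between two voxels is the Pearson correlation of
#' their preprocessed BOLD time series (the *temporal* correlation). The
#' *spatial* correlation between two voxels is the Pearson correlation of
#' their whole-brain temporal-correlation maps — their connectivity
#' fingerprints — and is derived from the temporal matrix, not from the raw
#' series. Both matrices are symmetric V x V with entries in `[-1, 1]`;
#' voxels flagged as zero-variance get all-zero rows and columns (including
#' the diagonal) so they can never pass a positive threshold.
#'
#' @name correlation_matrix
NULL

new_correlation_matrix <- function(values, flavor, geometry) {
  structure(list(values = values, flavor = flavor, geometry = geometry),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %s flavor, %d x %d\n",
              x$flavor, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Temporal correlation matrix of a BOLD series
#'
#' Pairwise Pearson correlations of the in-mask voxel time series, evaluated
#' in column blocks so the working set beyond the V x V result is bounded by
#' `block_size` voxels' worth of series.
#'
#' @param series a [bold_series()].
#' @param block_size number of voxels per block (the result matrix itself is
#'   always dense V x V).
#' @return A `correlation_matrix` with `flavor = "temporal"`.
#' @export
temporal_correlation_matrix <- function(series, block_size = 512L) {
  if (series$T < 3L)
    stop("input error: need at least 3 time points", call. = FALSE)
  X <- series$data
  V <- nrow(X)
  # standardize rows once; zero-variance rows become all-zero rows
  mu <- rowMeans(X)
  Xc <- X - mu
  ss <- sqrt(rowSums(Xc^2))
  nz <- ss > 0
  Xs <- Xc
  Xs[nz, ] <- Xc[nz, , drop = FALSE] / ss[nz]
  Xs[!nz, ] <- 0
  R <- matrix(0, V, V)
  starts <- seq(1L, V, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, V)
    R[, s:e] <- Xs %*% t(Xs[s:e, , drop = FALSE])
  }
  R <- (R + t(R)) / 2                       # enforce exact symmetry
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- ifelse(nz, 1, 0)
  new_correlation_matrix(R, "temporal", series$geometry)
}

#' Spatial correlation matrix from a temporal matrix
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the
#' temporal matrix with positions i and j removed from both rows: the
#' diagonal 1s and the r(i, j) entry itself would otherwise leak trivial
#' agreement into every pair. Pairs where either reduced row has zero
#' variance get 0. Evaluated with closed-form leave-two-out sums, O(V^2)
#' after one matrix product.
#'
#' @param temporal a `correlation_matrix` with `flavor = "temporal"`.
#' @return A `correlation_matrix` with `flavor = "spatial"`, diagonal 1
#'   (0 for zero-variance voxels).
#' @export
spatial_correlation_matrix <- function(temporal) {
  stopifnot(inherits(temporal, "correlation_matrix"))
  if (temporal$flavor != "temporal")
    stop("input error: spatial correlation requires a temporal matrix",
         call. = FALSE)
  M <- temporal$values
  V <- nrow(M)
  if (V < 4L)
    stop("input error: need V >= 4 for leave-two-out spatial correlation",
         call. = FALSE)
  d <- diag(M)
  r <- rowSums(M)
  q <- rowSums(M^2)
  A <- M %*% M                               # A[i,j] = sum_k M[i,k] M[j,k]
  n <- V - 2
  # leave-two-out sums for every pair (i,j), exploiting symmetry of M
  Sa <- outer(r - d, rep(1, V)) - M          # sum of row i without i, j
  Sb <- t(Sa)
  Qa <- outer(q - d^2, rep(1, V)) - M^2
  Qb <- t(Qa)
  Sab <- A - outer(d, rep(1, V)) * M - M * outer(rep(1, V), d)
  num <- n * Sab - Sa * Sb
  va <- n * Qa - Sa^2
  vb <- n * Qb - Sb^2
  va[va < 0] <- 0; vb[vb < 0] <- 0           # clip tiny negative round-off
  den <- sqrt(va * vb)
  S <- matrix(0, V, V)
  ok <- den > 0
  S[ok] <- num[ok] / den[ok]
  S <- (S + t(S)) / 2
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- ifelse(d == 0, 0, 1)            # zero-variance voxels stay degenerate
  new_correlation_matrix(S, "spatial", temporal$geometry)
}

#' Mean positive off-diagonal correlation
#'
#' Arithmetic mean of all strictly positive off-diagonal entries, each
#' unordered pair counted once (upper triangle). This is the "extremely low"
#' cutoff of the first filtering step in the adaptive-threshold procedure.
#'
#' @param matrix a `correlation_matrix`.
#' @return scalar in (0, 1].
#' @export
mean_positive_correlation <- function(matrix) {
  v <- matrix$values[upper.tri(matrix$values)]
  pos <- v[v > 0]
  if (length(pos) == 0L)
    stop("value error: no positive off-diagonal correlations", call. = FALSE)
  mean(pos)
}
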