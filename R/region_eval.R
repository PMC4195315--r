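#' Region-growing error rate
#'
#' Growing is performed independently from every seed, so membership need
#' not be symmetric: voxel j may fall in `C_i` while i is missing from
#' `C_j`. Each unordered pair where exactly one of the two memberships holds
#' counts one error; the rate divides by the total number of pairs
#' `V (V - 1) / 2`. A low rate indicates consistent growing.
#'
#' @param map a `cluster_map`.
#' @return scalar in `[0, 1]`.
#' @export
rger <- function(map) {
  V <- length(map$clusters)
  if (V < 2L) stop("input error: need at least 2 voxels", call. = FALSE)
  inC <- membership_matrix(map)           # inC[i, j] = TRUE iff j in C_i
  asym <- inC != t(inC)
  sum(asym[upper.tri(asym)]) / (V * (V - 1) / 2)
}

membership_matrix <- function(map) {
  V <- length(map$clusters)
  inC <- matrix(FALSE, V, V)
  for (i in seq_len(V)) inC[i, map$clusters[[i]]] <- TRUE
  inC
}

#' Type I and type II cluster-size maps
#'
#' `M_i = |C_i|` is the size of the cluster grown from voxel i (type I);
#' `N_i` counts the clusters that contain voxel i, including `C_i` itself
#' (type II), so perfectly symmetric growing gives `M = N` exactly. Note the
#' inclusive count: counting only *other* clusters would force
#' `M = N + 1` at perfection and break that identity. The two totals always
#' agree: `sum(M) = sum(N)` (both count membership incidences).
#'
#' @param map a `cluster_map`.
#' @return A tibble with columns `voxel`, `type_I` (M) and `type_II` (N).
#' @export
cluster_size_maps <- function(map) {
  inC <- membership_matrix(map)
  tibble::tibble(voxel = seq_len(nrow(inC)),
                 type_I = rowSums(inC),
                 type_II = colSums(inC))
}

#' Z-score a per-voxel map
#'
#' Standardizes to mean 0 over the mask using the population SD (divide by
#' N, not N - 1); the choice is recorded via the `ddof` argument.
#'
#' @param values numeric vector (a per-voxel map).
#' @param ddof delta degrees of freedom: 0 (population SD, default) or 1
#'   (sample SD).
#' @return numeric vector of z-scores.
#' @export
zscore_map <- function(values, ddof = 0) {
  n <- length(values)
  mu <- mean(values)
  sd_ <- sqrt(sum((values - mu)^2) / (n - ddof))
  if (!is.finite(sd_) || sd_ == 0)
    stop("value error: zero variance, z-scores undefined", call. = FALSE)
  (values - mu) / sd_
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve a 3D array along one axis with zero padding, by shifted adds
conv_axis <- function(arr, kernel, axis) {
  radius <- (length(kernel) - 1L) %/% 2L
  if (radius == 0L) return(arr * kernel)
  d <- dim(arr)
  out <- array(0, d)
  for (o in (-radius):radius) {
    w <- kernel[o + radius + 1L]
    src <- seq_len(d[axis]) + o
    ok <- src >= 1L & src <= d[axis]
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1L) out[idx_dst, , ] <- out[idx_dst, , ] + w * arr[idx_src, , ]
    else if (axis == 2L) out[, idx_dst, ] <- out[, idx_dst, ] + w * arr[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + w * arr[, , idx_src]
  }
  out
}

#' Gaussian smoothing of a masked map
#'
#' Separable 3D Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 ln 2))`
#' per axis in voxel units, using mask-normalized convolution: both the
#' zero-filled map and the binary mask are convolved with the same kernel
#' and their ratio is taken inside the mask. Out-of-mask voxels therefore
#' never dilute the result and a constant map is returned unchanged. `NaN`
#' voxels are excluded from the smoothing support the same way.
#'
#' @param values numeric vector of length `geometry$V`.
#' @param geometry a [mask_geometry()].
#' @param fwhm_mm kernel full width at half maximum, mm (default 8).
#' @return numeric vector of smoothed values on the mask.
#' @export
smooth_map <- function(values, geometry, fwhm_mm = 8) {
  stopifnot(fwhm_mm >= 0)
  if (length(values) != geometry$V)
    stop("input error: values length != geometry$V", call. = FALSE)
  if (fwhm_mm == 0) return(values)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / geometry$voxel_size
  lin <- which(!is.na(geometry$vox_index))
  vol <- array(0, geometry$dim)
  wt <- array(0, geometry$dim)
  finite <- is.finite(values)
  vol[lin[finite]] <- values[finite]
  wt[lin[finite]] <- 1
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    vol <- conv_axis(vol, k, axis)
    wt <- conv_axis(wt, k, axis)
  }
  out <- rep(NaN, geometry$V)
  num <- vol[lin]
  den <- wt[lin]
  out[den > 0] <- num[den > 0] / den[den > 0]
  out[!finite] <- NaN
  out
}

#' Intra-class correlation for two measurements across subjects
#'
#' Single-score two-way ICC from the standard mean squares (rows =
#' subjects, columns = the two measurements). The default variant "A1" is
#' two-way absolute agreement, single measurement (McGraw & Wong's
#' ICC(A,1)); "C1" is the consistency variant ICC(C,1).
#'
#' @param a,b numeric vectors, one value per subject (same length >= 3).
#' @param variant "A1" (absolute agreement, default) or "C1" (consistency).
#' @return scalar ICC in `[-1, 1]` (`NaN` if both measurements are constant).
#' @export
icc_pair <- function(a, b, variant = c("A1", "C1")) {
  variant <- match.arg(variant)
  as.numeric(icc_pair_vec(matrix(a, ncol = 1), matrix(b, ncol = 1), variant))
}

# vectorized over columns: A, B are subjects x voxels
icc_pair_vec <- function(A, B, variant = "A1") {
  n <- nrow(A)
  k <- 2
  m <- (colMeans(A) + colMeans(B)) / 2                 # grand mean per voxel
  s <- (A + B) / 2                                     # subject means
  msr <- k * colSums(sweep(s, 2, m)^2) / (n - 1)
  msc <- n * ((colMeans(A) - m)^2 + (colMeans(B) - m)^2) / (k - 1)
  resA <- sweep(A - s, 2, colMeans(A) - m)
  resB <- sweep(B - s, 2, colMeans(B) - m)
  mse <- (colSums(resA^2) + colSums(resB^2)) / ((n - 1) * (k - 1))
  if (variant == "A1") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Voxel-wise agreement between two sets of subject maps
#'
#' At every voxel, the ICC across subjects with the two map types as the
#' two measurements — e.g. type I vs type II cluster-size maps, both
#' z-scored and smoothed beforehand. Voxels where either measurement has
#' zero variance across subjects give `NaN`.
#'
#' @param maps_a,maps_b numeric matrices, subjects x voxels (equal shapes,
#'   >= 3 subjects).
#' @param variant see [icc_pair()].
#' @return numeric vector of per-voxel ICC values.
#' @export
map_agreement_icc <- function(maps_a, maps_b, variant = c("A1", "C1")) {
  variant <- match.arg(variant)
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (!all(dim(maps_a) == dim(maps_b)))
    stop("input error: map sets differ in shape", call. = FALSE)
  if (nrow(maps_a) < 3L)
    stop("input error: need at least 3 subjects", call. = FALSE)
  icc <- icc_pair_vec(maps_a, maps_b, variant)
  icc[!is.finite(icc)] <- NaN
  icc
}
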