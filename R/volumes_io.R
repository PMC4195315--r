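#' Load a masked 4D BOLD series
#'
#' Reads a 4D NIfTI volume and a 3D binary mask (nonzero = in-mask) and
#' returns the in-mask voxel time series in the deterministic voxel order of
#' [mask_geometry()]. The mask and BOLD grids must agree in shape and affine.
#' Voxels whose time series have zero variance are kept in the mask but
#' flagged: all their correlations are later defined as 0, which guarantees
#' they never pass a positive threshold without propagating `NaN`s.
#'
#' @param bold_path path to a 4D NIfTI (.nii/.nii.gz).
#' @param mask_path path to a 3D NIfTI mask on the same grid.
#' @return A `bold_series`: list with `data` (V x T matrix), `geometry`,
#'   `T`, and `zero_variance` (logical length V).
#' @export
load_bold <- function(bold_path, mask_path) {
  bold <- RNifti::readNifti(bold_path)
  mask <- RNifti::readNifti(mask_path)
  bdim <- dim(bold)
  if (length(bdim) == 3L) bdim <- c(bdim, 1L)
  if (length(dim(mask)) != 3L)
    stop("mask must be 3D", call. = FALSE)
  if (!all(bdim[1:3] == dim(mask)))
    stop("geometry error: BOLD and mask grids differ in shape", call. = FALSE)
  axf <- RNifti::xform(bold)[1:3, 1:3]
  mxf <- RNifti::xform(mask)[1:3, 1:3]
  if (max(abs(axf - mxf)) > 1e-4)
    stop("geometry error: BOLD and mask affines differ", call. = FALSE)
  vs <- RNifti::pixdim(mask)[1:3]
  geometry <- mask_geometry(array(mask != 0, dim(mask)), voxel_size = vs,
                            template = mask)
  nt <- bdim[4]
  dat <- matrix(as.numeric(bold), nrow = prod(bdim[1:3]), ncol = nt)
  lin <- which(array(mask != 0, dim(mask)))
  bold_series(dat[lin, , drop = FALSE], geometry)
}

#' Construct a BOLD series container from a matrix
#'
#' @param data V x T numeric matrix of in-mask time series, rows in the voxel
#'   order of `geometry`.
#' @param geometry a [mask_geometry()].
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, geometry) {
  data <- as.matrix(data)
  if (nrow(data) != geometry$V)
    stop("input error: data rows (", nrow(data), ") != geometry voxels (",
         geometry$V, ")", call. = FALSE)
  if (!all(is.finite(data)))
    stop("input error: non-finite values in BOLD data", call. = FALSE)
  rv <- if (ncol(data) < 2L) rep(0, nrow(data)) else apply(data, 1L, stats::var)
  structure(
    list(data = data, geometry = geometry, T = ncol(data),
         zero_variance = rv == 0),
    class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> V=%d voxels, T=%d time points (%d zero-variance)\n",
              x$geometry$V, x$T, sum(x$zero_variance)))
  invisible(x)
}

#' Write a per-voxel map as a NIfTI volume
#'
#' Out-of-mask voxels receive `background` (default 0). `NaN` values in the
#' map are preserved, not replaced by the background.
#'
#' @param values numeric vector of length `geometry$V`.
#' @param geometry a [mask_geometry()].
#' @param path output file path (.nii or .nii.gz).
#' @param background value outside the mask.
#' @return `path`, invisibly.
#' @export
write_map <- function(values, geometry, path, background = 0) {
  if (length(values) != geometry$V)
    stop("input error: values length != geometry$V", call. = FALSE)
  vol <- array(as.numeric(background), geometry$dim)
  vol[!is.na(geometry$vox_index)] <- as.numeric(values)
  img <- if (!is.null(geometry$template)) {
    RNifti::asNifti(vol, reference = geometry$template)
  } else {
    RNifti::asNifti(vol, pixdim = geometry$voxel_size)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a per-voxel map written by [write_map()]
#'
#' @inheritParams write_map
#' @param path NIfTI file to read.
#' @return numeric vector of length `geometry$V` in mask voxel order.
#' @export
read_map <- function(path, geometry) {
  vol <- RNifti::readNifti(path)
  if (!all(dim(vol)[1:3] == geometry$dim))
    stop("geometry error: map grid differs from mask grid", call. = FALSE)
  as.numeric(vol[!is.na(geometry$vox_index)])
}
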