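#' Mask geometry: voxel indexing and neighbourhoods
#'
#' A `mask_geometry` object fixes, once and for all, the mapping between
#' in-mask voxels and positions on the 3D acquisition grid. Voxels are
#' numbered `1..V` in ascending C-order linear index of the grid (last axis
#' fastest in the array sense of R, i.e. ascending `x + nx*y + nx*ny*z` with
#' 0-based grid coordinates), so voxel order is deterministic for a given
#' mask and every downstream structure (correlation matrix, cluster map,
#' degree map) indexes voxels the same way.
#'
#' @param mask logical or numeric 3D array; nonzero means in-mask.
#' @param voxel_size numeric length-3, physical edge lengths in mm.
#' @param template optional `RNifti` image whose header is reused when maps
#'   are written back to disk.
#' @return An object of class `mask_geometry` with fields `dim`, `voxel_size`,
#'   `coords` (V x 3 matrix of 0-based grid coordinates), `vox_index`
#'   (3D array mapping grid positions to voxel numbers, `NA` outside the
#'   mask) and `V`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2] <- TRUE
#' g <- mask_geometry(m)
#' g$V
#' @export
mask_geometry <- function(mask, voxel_size = c(1, 1, 1), template = NULL) {
  mask <- array(as.logical(mask != 0), dim = dim(mask))
  if (length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!any(mask)) stop("mask is empty: no in-mask voxels", call. = FALSE)
  lin <- which(mask)                      # ascending linear index = C-order contract
  dims <- dim(mask)
  coords <- arrayInd(lin, dims) - 1L      # 0-based internally
  vox_index <- array(NA_integer_, dims)
  vox_index[lin] <- seq_along(lin)
  structure(
    list(dim = dims,
         voxel_size = as.numeric(voxel_size),
         coords = coords,
         vox_index = vox_index,
         V = length(lin),
         template = template),
    class = "mask_geometry")
}

#' @export
print.mask_geometry <- function(x, ...) {
  cat(sprintf("<mask_geometry> %d voxels on a %s grid (voxel %s mm)\n",
              x$V, paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x")))
  invisible(x)
}

# offset tables for the two connectivities
offsets_for <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 26L))
  if (connectivity == 6L) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
          c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' In-mask neighbours of every voxel
#'
#' Face (6) or full cubic (26) neighbourhoods restricted to the mask; a voxel
#' is never its own neighbour.
#'
#' @param geometry a [mask_geometry()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return list of length `V`; element `i` holds the voxel numbers of the
#'   in-mask neighbours of voxel `i` (possibly empty).
#' @export
neighbor_list <- function(geometry, connectivity = 26L) {
  off <- offsets_for(as.integer(connectivity))
  dims <- geometry$dim
  V <- geometry$V
  hits <- matrix(NA_integer_, nrow = V, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    nc <- sweep(geometry$coords, 2L, off[k, ], `+`)
    ok <- nc[, 1] >= 0 & nc[, 1] < dims[1] &
          nc[, 2] >= 0 & nc[, 2] < dims[2] &
          nc[, 3] >= 0 & nc[, 3] < dims[3]
    idx <- rep(NA_integer_, V)
    idx[ok] <- geometry$vox_index[nc[ok, , drop = FALSE] + 1L]
    hits[, k] <- idx
  }
  lapply(seq_len(V), function(i) {
    h <- hits[i, ]
    h[!is.na(h)]
  })
}
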