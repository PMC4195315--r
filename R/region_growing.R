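#' Seed-based region growing over 26-connectivity
#'
#' For every seed voxel i the cluster `C_i` starts as `{i}` and iteratively
#' absorbs any 26-neighbour j of the current cluster whose correlation with
#' the *seed* satisfies `r(i, j) >= T_a`, until no voxel can be added. The
#' criterion always refers back to the seed (the correlation matrix is fixed
#' across iterations), so the fixed point is independent of visit order.
#' Clusters from different seeds may overlap or disagree; that inconsistency
#' is exactly what [rger()] measures.
#'
#' @param matrix a `correlation_matrix`.
#' @param seed voxel number.
#' @param T_a growth threshold in (0, 1).
#' @param geometry [mask_geometry()] (defaults to the matrix's own).
#' @param nbrs26 optional precomputed [neighbor_list()] with connectivity 26.
#' @return integer vector of cluster member voxel numbers (sorted, seed
#'   always included).
#' @export
grow_region <- function(matrix, seed, T_a, geometry = matrix$geometry,
                        nbrs26 = NULL) {
  stopifnot(T_a > 0, T_a < 1)
  if (is.null(nbrs26)) nbrs26 <- neighbor_list(geometry, 26L)
  r <- matrix$values[seed, ]
  eligible <- r >= T_a
  eligible[seed] <- TRUE
  member <- logical(geometry$V)
  member[seed] <- TRUE
  frontier <- seed
  while (length(frontier) > 0L) {
    cand <- unique(unlist(nbrs26[frontier], use.names = FALSE))
    cand <- cand[!member[cand] & eligible[cand]]
    member[cand] <- TRUE
    frontier <- cand
  }
  which(member)
}

#' Region growing from every seed voxel
#'
#' @inheritParams grow_region
#' @return A `cluster_map`: list with `clusters` (list of integer vectors,
#'   one per seed), `flavor` (inherited from `matrix`), `T_a_used`,
#'   `geometry`.
#' @export
grow_all <- function(matrix, T_a, geometry = matrix$geometry) {
  nbrs26 <- neighbor_list(geometry, 26L)
  clusters <- lapply(seq_len(geometry$V), function(i) {
    grow_region(matrix, i, T_a, geometry, nbrs26)
  })
  new_cluster_map(clusters, matrix$flavor, T_a, geometry)
}

new_cluster_map <- function(clusters, flavor, T_a_used, geometry) {
  structure(list(clusters = clusters, flavor = flavor,
                 T_a_used = T_a_used, geometry = geometry),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  sz <- lengths(x$clusters)
  cat(sprintf("<cluster_map> %s flavor, %d seeds, cluster sizes %d-%d (T_a = %.3f)\n",
              x$flavor, length(x$clusters), min(sz), max(sz), x$T_a_used))
  invisible(x)
}

#' Intersect temporal and spatial cluster maps
#'
#' Temporal and spatial correlations capture different connectivity
#' features; intersecting the two region-growing results gives the combined
#' per-voxel region estimate used by the corrected degree metrics. The
#' intersection may be disconnected; members are kept as-is since the degree
#' formulas only use membership.
#'
#' @param temporal,spatial `cluster_map`s with flavors "temporal" and
#'   "spatial" on the same geometry.
#' @return A `cluster_map` with `flavor = "combined"`.
#' @export
combine_cluster_maps <- function(temporal, spatial) {
  if (!identical(temporal$geometry$dim, spatial$geometry$dim) ||
      temporal$geometry$V != spatial$geometry$V)
    stop("input error: cluster maps have different geometries", call. = FALSE)
  clusters <- Map(intersect, temporal$clusters, spatial$clusters)
  clusters <- lapply(clusters, sort)
  new_cluster_map(clusters, "combined",
                  mean(c(temporal$T_a_used, spatial$T_a_used)), temporal$geometry)
}

#' Label voxels by their grown cluster
#'
#' Assigns each seed voxel an integer label such that two voxels share a
#' label iff their clusters contain exactly the same voxel set. Useful for
#' comparing region-growing output against ground-truth parcels (e.g. with
#' an adjusted Rand index).
#'
#' @param map a `cluster_map`.
#' @return integer vector of length V.
#' @export
cluster_labels <- function(map) {
  keys <- vapply(map$clusters, function(cl) paste(cl, collapse = ","), character(1))
  match(keys, unique(keys))
}
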