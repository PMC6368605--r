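#' Generate a synthetic parcellation atlas
#'
#' Creates an ellipsoidal brain mask on a regular voxel grid and partitions it
#' into `n_regions` contiguous regions by seeded nearest-centroid growth:
#' `n_regions` mask voxels are drawn as region seeds and every mask voxel is
#' assigned to its nearest seed (Euclidean distance in voxel space, ties to
#' the lowest seed index). The result mimics an anatomical labelling such as
#' the 54 left-hemisphere AAL regions used for regional statistics.
#'
#' @param grid_shape integer vector of length 3, voxels per axis (each >= 8).
#' @param n_regions number of regions, between 2 and the mask voxel count.
#' @param seed integer seed; the atlas is a pure function of it.
#' @param affine optional 4x4 voxel-to-world transform (defaults to identity).
#'
#' @return An object of class `voxgex_atlas`: a list with `grid_shape`,
#'   `affine`, `mask` (logical array), `labels` (integer array, 0 outside the
#'   mask), and `region_names` (character vector indexed by label).
#' @export
make_atlas <- function(grid_shape, n_regions, seed, affine = diag(4)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("grid_shape must be three integers, each >= 8")
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 2L)
    stop("n_regions must be a single integer >= 2")
  n_regions <- as.integer(n_regions)

  ctr <- (grid_shape - 1) / 2
  semi <- 0.42 * grid_shape
  ax <- (seq_len(grid_shape[1]) - 1 - ctr[1]) / semi[1]
  ay <- (seq_len(grid_shape[2]) - 1 - ctr[2]) / semi[2]
  az <- (seq_len(grid_shape[3]) - 1 - ctr[3]) / semi[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  mask <- array(r2 <= 1, dim = grid_shape)

  vox <- mask_coords(mask)
  n_mask <- nrow(vox)
  if (n_regions > n_mask)
    stop("n_regions (", n_regions, ") exceeds the mask voxel count (", n_mask, ")")

  centroid_idx <- withr::with_seed(seed, sample.int(n_mask, n_regions))
  cen <- vox[centroid_idx, , drop = FALSE]
  d2 <- outer(rowSums(vox^2), rep(1, n_regions)) +
    outer(rep(1, n_mask), rowSums(cen^2)) - 2 * vox %*% t(cen)
  lab_vec <- max.col(-d2, ties.method = "first")

  labels <- array(0L, dim = grid_shape)
  labels[mask] <- as.integer(lab_vec)

  structure(
    list(
      grid_shape = grid_shape,
      affine = affine,
      mask = mask,
      labels = labels,
      region_names = sprintf("region_%02d", seq_len(n_regions))
    ),
    class = "voxgex_atlas"
  )
}

#' Voxel coordinates of a mask
#'
#' Returns the 0-based integer voxel coordinates of all `TRUE` voxels of a
#' logical volume, in column-major (lexicographic x-fastest) order.
#'
#' @param mask logical 3D array, or a `voxgex_atlas`.
#' @return numeric matrix with one row per mask voxel and columns x, y, z.
#' @export
mask_coords <- function(mask) {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  idx <- which(mask)
  dm <- dim(mask)
  i <- (idx - 1L) %% dm[1]
  j <- ((idx - 1L) %/% dm[1]) %% dm[2]
  k <- (idx - 1L) %/% (dm[1] * dm[2])
  cbind(x = as.numeric(i), y = as.numeric(j), z = as.numeric(k))
}

# linear array index of 0-based integer voxel coordinates
voxel_index <- function(coords, dim) {
  1L + coords[, 1] + dim[1] * (coords[, 2] + dim[2] * coords[, 3])
}

#' Region label of continuous voxel coordinates
#'
#' Rounds continuous 0-based voxel coordinates to the nearest voxel and looks
#' up the atlas label there.
#'
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @param atlas a `voxgex_atlas`.
#' @return integer vector of region labels (0 = outside the mask).
#' @export
region_at <- function(coords, atlas) {
  vox <- round(coords)
  if (any(vox < 0) || any(sweep(vox, 2, atlas$grid_shape - 1) > 0))
    stop("coordinates outside the atlas grid")
  as.integer(atlas$labels[voxel_index(vox, atlas$grid_shape)])
}

#' @export
print.voxgex_atlas <- function(x, ...) {
  cat("voxgex_atlas:", paste(x$grid_shape, collapse = " x "), "grid,",
      sum(x$mask), "mask voxels,", length(x$region_names), "regions\n")
  invisible(x)
}
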