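# Dense voxel maps from scattered samples: border labelling, Delaunay
# tessellation, barycentric interpolation, donor averaging.

#' Find the border voxels of a mask
#'
#' A border voxel is a mask voxel with at least one 6-connected neighbour
#' outside the mask or beyond the grid edge. The result is sorted
#' lexicographically (x, then y, then z) for determinism.
#'
#' @param mask logical 3D array, or a `voxgex_atlas`.
#' @return numeric matrix of 0-based voxel coordinates, one row per border
#'   voxel.
#' @export
find_border_voxels <- function(mask) {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  if (!any(mask)) stop("empty mask")
  dm <- dim(mask)
  pad <- array(FALSE, dm + 2L)
  pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] <- mask
  interior <- pad[2:(dm[1] + 1), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[1:dm[1], 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[3:(dm[1] + 2), 2:(dm[2] + 1), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 1:dm[2], 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 3:(dm[2] + 2), 2:(dm[3] + 1)] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 1:dm[3]] &
    pad[2:(dm[1] + 1), 2:(dm[2] + 1), 3:(dm[3] + 2)]
  border <- mask & !interior
  xyz <- mask_coords(border)
  xyz[order(xyz[, 1], xyz[, 2], xyz[, 3]), , drop = FALSE]
}

#' Label border voxels with their nearest sample's expression value
#'
#' Each border voxel becomes a pseudo-point at the voxel centre carrying the
#' expression value of the nearest sample (Euclidean distance in voxel
#' space; ties go to the lowest sample index). The returned point set is the
#' original samples followed by the border pseudo-points.
#'
#' @param samples a `voxgex_donor_samples`.
#' @param gene_id single gene id, or a character vector of gene ids (the
#'   value matrix then has one column per gene).
#' @param border_voxels matrix of 0-based border voxel coordinates, as from
#'   [find_border_voxels()].
#' @return list with `coords` ((n_samples + n_border) x 3), `values`
#'   (matrix with one column per requested gene), `n_samples`.
#' @export
label_borders <- function(samples, gene_id, border_voxels) {
  stopifnot(inherits(samples, "voxgex_donor_samples"))
  if (nrow(samples$coords) < 1L) stop("need at least one sample")
  missing_genes <- setdiff(gene_id, samples$gene_ids)
  if (length(missing_genes))
    stop("unknown gene id(s): ", paste(missing_genes, collapse = ", "))
  nn <- .cpp_nearest(samples$coords, border_voxels)
  vals <- samples$expression[, gene_id, drop = FALSE]
  list(
    coords = rbind(samples$coords, border_voxels),
    values = rbind(vals, vals[nn, , drop = FALSE]),
    n_samples = nrow(samples$coords)
  )
}

# deterministic sub-voxel jitter used to put grid-aligned pseudo-points into
# generic position; a pure hash of the point index, no RNG state touched
.jitter_points <- function(pts, magnitude) {
  n <- nrow(pts)
  h <- function(k) {
    x <- sin(seq_len(n) * 127.1 + k * 311.7) * 43758.5453123
    x - floor(x)
  }
  pts + magnitude * (cbind(h(1), h(2), h(3)) - 0.5)
}

#' Build a 3D Delaunay tessellation
#'
#' Tessellates a scattered 3D point set into tetrahedra (Bowyer-Watson
#' incremental insertion). A deterministic jitter of relative magnitude
#' `1e-6` is applied internally to put grid-aligned points into generic
#' position; barycentric weights are later computed from the original
#' coordinates, so interpolation remains exact on affine fields.
#'
#' @param points n x 3 coordinate matrix, n >= 4, not all coplanar.
#' @return An object of class `voxgex_tessellation`: list with `points`
#'   (original), `jittered`, and `simplices` (m x 4 matrix of 1-based vertex
#'   indices).
#' @export
delaunay_tessellation <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 4L) stop("need at least 4 points")
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 0)$d
  scale <- max(1, sv[1])
  if (length(sv) < 3 || sv[3] < 1e-9 * scale)
    stop("degenerate (coplanar or collinear) point set; jitter the points")
  span <- max(1, apply(points, 2, function(v) diff(range(v))))
  jit <- .jitter_points(points, 1e-6 * span)
  simplices <- .cpp_delaunay(jit)
  structure(
    list(points = points, jittered = jit, simplices = simplices),
    class = "voxgex_tessellation"
  )
}

#' Interpolate scattered values at query points
#'
#' Evaluates the piecewise-linear (barycentric) interpolant of the
#' tessellation at each query point. Queries outside the convex hull fall
#' back to the nearest data point's value (or NA).
#'
#' @param tess a `voxgex_tessellation`.
#' @param values numeric vector (length n points) or matrix (n x q) of
#'   point values.
#' @param queries m x 3 matrix of query coordinates.
#' @param fallback "nearest" (default) or "na" for out-of-hull queries.
#' @return numeric vector (or matrix, matching `values`) of interpolated
#'   values; attribute `"in_hull"` is a logical vector.
#' @export
delaunay_interpolate <- function(tess, values, queries,
                                 fallback = c("nearest", "na")) {
  stopifnot(inherits(tess, "voxgex_tessellation"))
  fallback <- match.arg(fallback)
  queries <- as.matrix(queries)
  storage.mode(queries) <- "double"
  vec_in <- is.null(dim(values))
  V <- if (vec_in) matrix(values, ncol = 1) else as.matrix(values)
  if (nrow(V) != nrow(tess$points))
    stop("values must have one entry per tessellation point")

  w <- .cpp_interp_weights(tess$points, tess$jittered, tess$simplices,
                           queries, 1e-9)
  in_hull <- !is.na(w$simplex)
  out <- matrix(NA_real_, nrow(queries), ncol(V))
  if (any(in_hull)) {
    idx <- w$vertices[in_hull, , drop = FALSE]
    wt <- w$weights[in_hull, , drop = FALSE]
    acc <- wt[, 1] * V[idx[, 1], , drop = FALSE]
    for (k in 2:4) acc <- acc + wt[, k] * V[idx[, k], , drop = FALSE]
    out[in_hull, ] <- acc
  }
  if (fallback == "nearest" && any(!in_hull)) {
    nn <- .cpp_nearest(tess$points, queries[!in_hull, , drop = FALSE])
    out[!in_hull, ] <- V[nn, , drop = FALSE]
  }
  colnames(out) <- colnames(V)
  res <- if (vec_in) drop(out) else out
  attr(res, "in_hull") <- in_hull
  res
}

#' Interpolate an augmented point set onto a mask
#'
#' Builds the Delaunay tessellation of the (border-labelled) point set and
#' evaluates the barycentric interpolant at every mask voxel centre. Mask
#' voxels outside the convex hull take the nearest point's value. Values are
#' clamped to the input value range (linear interpolation of border-labelled
#' data cannot legitimately extrapolate beyond it).
#'
#' @param points n x 3 coordinates (samples plus border pseudo-points).
#' @param values numeric vector of point values (one gene).
#' @param mask logical 3D array or `voxgex_atlas`.
#' @param gene_id,donor_id provenance strings.
#' @return An object of class `voxgex_expression_volume`: list with
#'   `gene_id`, `donor_id`, `values` (3D array, NA outside the mask) and
#'   `provenance`.
#' @export
interpolate_volume <- function(points, values, mask,
                               gene_id = "gene", donor_id = "donor") {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  tess <- delaunay_tessellation(points)
  q <- mask_coords(mask)
  v <- delaunay_interpolate(tess, values, q, fallback = "nearest")
  rng <- range(values)
  v <- pmin(pmax(as.numeric(v), rng[1]), rng[2])
  vol <- array(NA_real_, dim = dim(mask))
  vol[mask] <- v
  structure(
    list(gene_id = gene_id, donor_id = donor_id, values = vol,
         provenance = list(n_points = nrow(points),
                           n_simplices = nrow(tess$simplices))),
    class = "voxgex_expression_volume"
  )
}

#' Build dense expression volumes for all genes of one donor
#'
#' The efficient multi-gene driver: border voxels are labelled once, the
#' tessellation (whose geometry is shared by all genes of a donor) is built
#' once, and all genes are interpolated through the same barycentric
#' weights.
#'
#' @param samples a `voxgex_donor_samples`.
#' @param atlas a `voxgex_atlas`.
#' @param gene_ids genes to map (default: all in the sample set).
#' @return An object of class `voxgex_volume_set`: list with `values`
#'   (mask-voxel x gene matrix), `mask_idx`, `grid_shape`, `gene_ids`,
#'   `donor_id`, `provenance`.
#' @export
build_expression_volumes <- function(samples, atlas, gene_ids = NULL) {
  stopifnot(inherits(samples, "voxgex_donor_samples"),
            inherits(atlas, "voxgex_atlas"))
  if (is.null(gene_ids)) gene_ids <- samples$gene_ids
  border <- find_border_voxels(atlas$mask)
  aug <- label_borders(samples, gene_ids, border)
  tess <- delaunay_tessellation(aug$coords)
  q <- mask_coords(atlas)
  v <- delaunay_interpolate(tess, aug$values, q, fallback = "nearest")
  v <- matrix(as.numeric(v), nrow(q), length(gene_ids),
              dimnames = list(NULL, gene_ids))
  # clamp per gene to the sample value range
  for (g in seq_along(gene_ids)) {
    rng <- range(samples$expression[, gene_ids[g]])
    v[, g] <- pmin(pmax(v[, g], rng[1]), rng[2])
  }
  structure(
    list(values = v, mask_idx = which(atlas$mask),
         grid_shape = atlas$grid_shape, gene_ids = gene_ids,
         donor_id = samples$donor_id,
         provenance = list(n_samples = nrow(samples$coords),
                           n_border = nrow(border),
                           n_simplices = nrow(tess$simplices))),
    class = "voxgex_volume_set"
  )
}

#' Extract one gene's 3D volume from a volume set
#'
#' @param vset a `voxgex_volume_set`.
#' @param gene_id gene to extract.
#' @return a `voxgex_expression_volume`.
#' @export
get_volume <- function(vset, gene_id) {
  stopifnot(inherits(vset, "voxgex_volume_set"))
  if (!gene_id %in% vset$gene_ids) stop("unknown gene id: ", gene_id)
  vol <- array(NA_real_, dim = vset$grid_shape)
  vol[vset$mask_idx] <- vset$values[, gene_id]
  structure(
    list(gene_id = gene_id, donor_id = vset$donor_id, values = vol,
         provenance = vset$provenance),
    class = "voxgex_expression_volume"
  )
}

#' Average expression volumes across donors
#'
#' Voxelwise arithmetic mean at mask voxels, so that each gene is
#' represented by a single donor-averaged map.
#'
#' @param volumes list of `voxgex_volume_set` (one per donor) on identical
#'   grids, or a list of `voxgex_expression_volume` for a single gene.
#' @return object of the same class as the inputs with
#'   `donor_id = "average"`.
#' @export
average_volumes <- function(volumes) {
  if (inherits(volumes, c("voxgex_volume_set", "voxgex_expression_volume")))
    volumes <- list(volumes)
  if (!length(volumes)) stop("need at least one volume")
  if (inherits(volumes[[1]], "voxgex_volume_set")) {
    ref <- volumes[[1]]
    for (v in volumes) {
      if (!identical(v$grid_shape, ref$grid_shape) ||
          !identical(v$mask_idx, ref$mask_idx) ||
          !identical(v$gene_ids, ref$gene_ids))
        stop("volume sets have mismatching grids or gene sets")
    }
    acc <- Reduce(`+`, lapply(volumes, `[[`, "values")) / length(volumes)
    out <- ref
    out$values <- acc
    out$donor_id <- "average"
    out$provenance <- list(n_donors = length(volumes))
    return(out)
  }
  ref <- volumes[[1]]
  for (v in volumes)
    if (!identical(dim(v$values), dim(ref$values)))
      stop("volumes have mismatching grids")
  acc <- Reduce(`+`, lapply(volumes, `[[`, "values")) / length(volumes)
  structure(
    list(gene_id = ref$gene_id, donor_id = "average", values = acc,
         provenance = list(n_donors = length(volumes))),
    class = "voxgex_expression_volume"
  )
}

#' @export
print.voxgex_volume_set <- function(x, ...) {
  cat("voxgex_volume_set:", x$donor_id, "-", length(x$mask_idx),
      "mask voxels,", length(x$gene_ids), "genes\n")
  invisible(x)
}
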