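# Reading and writing the pipeline's on-disk formats: NIfTI volumes,
# TSV sample tables, GMT-style gene sets, JSON sidecars.

#' Write an atlas as NIfTI volumes with a JSON sidecar
#'
#' Writes `<prefix>_mask.nii.gz`, `<prefix>_labels.nii.gz` and
#' `<prefix>.json` (grid shape, affine, region names).
#'
#' @param atlas a `voxgex_atlas`.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "voxgex_atlas"))
  paths <- c(mask = paste0(prefix, "_mask.nii.gz"),
             labels = paste0(prefix, "_labels.nii.gz"),
             meta = paste0(prefix, ".json"))
  RNifti::writeNifti(array(as.integer(atlas$mask), dim = atlas$grid_shape),
                     paths["mask"])
  RNifti::writeNifti(atlas$labels, paths["labels"])
  jsonlite::write_json(
    list(grid_shape = atlas$grid_shape, affine = atlas$affine,
         region_names = atlas$region_names),
    paths["meta"], auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  invisible(paths)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param prefix path prefix used when writing.
#' @return a `voxgex_atlas`.
#' @export
read_atlas <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mask_img <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  labels_img <- RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))
  gs <- as.integer(meta$grid_shape)
  structure(
    list(grid_shape = gs,
         affine = matrix(unlist(meta$affine), 4, 4, byrow = TRUE),
         mask = array(as.array(mask_img) != 0, dim = gs),
         labels = array(as.integer(as.array(labels_img)), dim = gs),
         region_names = as.character(meta$region_names)),
    class = "voxgex_atlas"
  )
}

#' Write a donor sample set as TSV
#'
#' Columns: `donor_id`, `x`, `y`, `z`, then one column per gene.
#'
#' @param samples a `voxgex_donor_samples`.
#' @param path output file.
#' @export
write_samples_tsv <- function(samples, path) {
  stopifnot(inherits(samples, "voxgex_donor_samples"))
  df <- data.frame(donor_id = samples$donor_id, samples$coords,
                   samples$expression, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a donor sample set written by [write_samples_tsv()]
#'
#' @param path TSV file.
#' @return a `voxgex_donor_samples`.
#' @export
read_samples_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  gene_ids <- setdiff(names(df), c("donor_id", "x", "y", "z"))
  structure(
    list(donor_id = as.character(df$donor_id[1]),
         coords = as.matrix(df[, c("x", "y", "z")]),
         expression = as.matrix(df[, gene_ids, drop = FALSE]),
         gene_ids = gene_ids),
    class = "voxgex_donor_samples"
  )
}

#' Write an expression volume (or one gene of a volume set) as NIfTI
#'
#' NA voxels outside the mask are written as 0.
#'
#' @param volume a `voxgex_expression_volume`.
#' @param path output `.nii.gz` path.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "voxgex_expression_volume"))
  v <- volume$values
  v[is.na(v)] <- 0
  RNifti::writeNifti(v, path)
  invisible(path)
}

#' Write a term map as paired Z / FDR-p NIfTI volumes
#'
#' Writes `<dir>/<term>_z.nii.gz` and `<dir>/<term>_pfdr.nii.gz`.
#'
#' @param term_map a `voxgex_term_map`.
#' @param dir output directory.
#' @export
write_term_map <- function(term_map, dir) {
  z <- term_map$z; z[is.na(z)] <- 0
  p <- term_map$p_fdr; p[is.na(p)] <- 1
  RNifti::writeNifti(z, file.path(dir, paste0(term_map$term, "_z.nii.gz")))
  RNifti::writeNifti(p, file.path(dir, paste0(term_map$term, "_pfdr.nii.gz")))
  invisible(term_map$term)
}

#' Read GMT-style gene sets
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write GMT-style gene sets
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (defaults to the set
#'   names).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
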