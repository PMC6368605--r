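# Differential stability: donor-to-donor reproducibility of a gene's
# spatial expression pattern.

#' Differential stability of a gene across donors
#'
#' Spearman's correlation of the gene's spatial profile for every unordered
#' donor pair, averaged into a single differential stability (DS) value.
#' Profiles are compared over the units both donors share (atlas region
#' means, or mask voxels of the donors' dense maps). Each pair's two-sided
#' p-value uses the t approximation at an effective sample size equal to
#' the smaller of the two donors' sample counts, the convention for maps
#' built from limited and variable numbers of samples.
#'
#' @param donor_profiles units x donor numeric matrix (or a named list of
#'   named numeric vectors), >= 2 donors; NA marks units absent for a
#'   donor.
#' @param gene_id identifier carried into the result.
#' @param sample_sizes optional named per-donor sample counts used for the
#'   pair p-values; defaults to each donor's non-missing unit count.
#' @return An object of class `voxgex_stability`: list with `gene_id`,
#'   `pairs` (data.frame: `donor_a`, `donor_b`, `r`, `n_units`, `n_eff`,
#'   `p`, `excluded`), `ds` (mean r over included pairs) and `n_pairs`.
#' @export
differential_stability <- function(donor_profiles, gene_id = "gene",
                                   sample_sizes = NULL) {
  if (is.list(donor_profiles) && !is.data.frame(donor_profiles)) {
    units <- Reduce(union, lapply(donor_profiles, names))
    m <- sapply(donor_profiles, function(p) unname(p[units]))
    rownames(m) <- units
    donor_profiles <- m
  }
  m <- as.matrix(donor_profiles)
  nd <- ncol(m)
  if (nd < 2L) stop("need at least 2 donors")
  donors <- colnames(m)
  if (is.null(donors)) donors <- paste0("donor_", seq_len(nd))
  if (is.null(sample_sizes)) {
    sample_sizes <- colSums(!is.na(m))
    names(sample_sizes) <- donors
  }
  pr <- combn(nd, 2)
  rows <- lapply(seq_len(ncol(pr)), function(q) {
    i <- pr[1, q]; j <- pr[2, q]
    ok <- complete.cases(m[, c(i, j)])
    n_units <- sum(ok)
    if (n_units < 3L)
      return(data.frame(donor_a = donors[i], donor_b = donors[j],
                        r = NA_real_, n_units = n_units, n_eff = NA_integer_,
                        p = NA_real_, excluded = TRUE,
                        stringsAsFactors = FALSE))
    r <- cor(m[ok, i], m[ok, j], method = "spearman")
    n_eff <- min(sample_sizes[donors[i]], sample_sizes[donors[j]])
    data.frame(donor_a = donors[i], donor_b = donors[j], r = r,
               n_units = n_units, n_eff = as.integer(n_eff),
               p = .spearman_p(r, n_eff), excluded = FALSE,
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(
    list(gene_id = gene_id, pairs = pairs,
         ds = mean(pairs$r[!pairs$excluded]),
         n_pairs = sum(!pairs$excluded)),
    class = "voxgex_stability"
  )
}

#' @export
print.voxgex_stability <- function(x, ...) {
  cat("voxgex_stability:", x$gene_id, "- DS =", format(x$ds, digits = 4),
      "over", x$n_pairs, "donor pairs\n")
  invisible(x)
}

#' Decile rank of a DS value within a gene library
#'
#' Decile 1 contains the top 10% of differential stability values; ties are
#' assigned the better decile.
#'
#' @param ds_value the gene's DS.
#' @param library_ds_values DS values of the full library (nonempty).
#' @return integer decile in 1..10.
#' @export
decile_rank <- function(ds_value, library_ds_values) {
  lib <- library_ds_values[!is.na(library_ds_values)]
  if (!length(lib)) stop("library of DS values is empty")
  rk <- 1L + sum(lib > ds_value)
  as.integer(ceiling(10 * rk / length(lib)))
}
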