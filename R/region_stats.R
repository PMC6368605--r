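# Regional summaries and enrichment statistics.

#' Region-by-donor mean expression matrix
#'
#' Computes one gene's mean expression per atlas region for each donor,
#' either from the donors' dense voxel maps (mean over the region's mask
#' voxels) or directly from the scattered samples falling inside each
#' region. Regions with no samples for a donor are NA in sample mode;
#' regions missing in every donor are dropped with a warning.
#'
#' @param donors list of `voxgex_volume_set` (mode "voxel") or of
#'   `voxgex_donor_samples` (mode "sample"), one per donor.
#' @param atlas a `voxgex_atlas`.
#' @param gene_id gene to summarise.
#' @param mode "voxel" or "sample".
#' @return region x donor numeric matrix (rownames = region names).
#' @export
region_means <- function(donors, atlas, gene_id, mode = c("voxel", "sample")) {
  stopifnot(inherits(atlas, "voxgex_atlas"))
  mode <- match.arg(mode)
  if (inherits(donors, c("voxgex_volume_set", "voxgex_donor_samples")))
    donors <- list(donors)
  n_regions <- length(atlas$region_names)
  region_ids <- seq_len(n_regions)
  out <- sapply(donors, function(d) {
    if (mode == "voxel") {
      stopifnot(inherits(d, "voxgex_volume_set"))
      lab <- atlas$labels[d$mask_idx]
      vals <- d$values[, gene_id]
      vapply(region_ids, function(r) mean(vals[lab == r]), numeric(1))
    } else {
      stopifnot(inherits(d, "voxgex_donor_samples"))
      lab <- region_at(d$coords, atlas)
      vals <- d$expression[, gene_id]
      vapply(region_ids, function(r) {
        inr <- lab == r
        if (!any(inr)) NA_real_ else mean(vals[inr])
      }, numeric(1))
    }
  })
  out <- matrix(out, nrow = n_regions,
                dimnames = list(atlas$region_names,
                                vapply(donors, `[[`, "", "donor_id")))
  all_missing <- rowSums(!is.na(out)) == 0L
  if (any(all_missing)) {
    warning("dropping region(s) with no data in any donor: ",
            paste(rownames(out)[all_missing], collapse = ", "))
    out <- out[!all_missing, , drop = FALSE]
  }
  out
}

#' Regional enrichment against the brain-wide average
#'
#' For each region, a two-tailed one-sample t-test of the donors' region
#' means against the grand mean (the mean over regions of the per-donor
#' region means, averaged over donors, treated as a fixed reference), with
#' Benjamini-Hochberg adjustment across regions and a one-sample Cohen's d
#' (`|mean - reference| / SD` of the donor region means).
#'
#' @param region_donor_matrix region x donor matrix, as from
#'   [region_means()].
#' @param grand_mean optional fixed reference; defaults to the mean of the
#'   matrix (every region weighted equally).
#' @return data.frame with one row per region: `region`, `n_donors`,
#'   `mean`, `t_stat`, `p_raw`, `p_fdr`, `cohens_d`, `direction`,
#'   `degenerate`; the reference is attached as attribute `"grand_mean"`.
#' @export
region_enrichment <- function(region_donor_matrix, grand_mean = NULL) {
  m <- as.matrix(region_donor_matrix)
  if (ncol(m) < 2L) stop("need at least 2 donors")
  if (is.null(grand_mean)) grand_mean <- mean(colMeans(m, na.rm = TRUE))
  rows <- lapply(seq_len(nrow(m)), function(r) {
    x <- m[r, ]
    x <- x[!is.na(x)]
    n <- length(x)
    xb <- mean(x)
    s <- sd(x)
    if (n < 2L || s == 0) {
      degen <- TRUE
      if (n >= 1L && xb == grand_mean) {
        t_stat <- 0; p <- 1; d <- 0
      } else {
        t_stat <- sign(xb - grand_mean) * Inf; p <- 0; d <- Inf
      }
    } else {
      degen <- FALSE
      t_stat <- (xb - grand_mean) / (s / sqrt(n))
      p <- 2 * pt(-abs(t_stat), df = n - 1)
      d <- abs(xb - grand_mean) / s
    }
    data.frame(region = rownames(m)[r], n_donors = n, mean = xb,
               t_stat = t_stat, p_raw = p, cohens_d = d,
               direction = if (xb >= grand_mean) "above" else "below",
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- p.adjust(out$p_raw, method = "BH")
  out <- out[, c("region", "n_donors", "mean", "t_stat", "p_raw", "p_fdr",
                 "cohens_d", "direction", "degenerate")]
  attr(out, "grand_mean") <- grand_mean
  out
}

#' Contrast mean expression between two groups of regions
#'
#' Welch two-sample two-tailed t-test on per-region expression (averaged
#' over donors) between two disjoint groups of regions, e.g. hypothalamic
#' versus thalamic substructures.
#'
#' @param region_donor_matrix region x donor matrix.
#' @param group_a,group_b character vectors of region names (or integer row
#'   indices); must be nonempty and disjoint.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
group_contrast <- function(region_donor_matrix, group_a, group_b) {
  m <- as.matrix(region_donor_matrix)
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  lvl <- rowMeans(m, na.rm = TRUE)
  a <- lvl[group_a]
  b <- lvl[group_b]
  if (anyNA(a) || anyNA(b)) stop("unknown region in group definition")
  if ((length(a) < 2L || var(a) == 0) && (length(b) < 2L || var(b) == 0))
    stop("cannot form a t statistic from degenerate groups")
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Spearman correlation between two regional expression profiles
#'
#' Rank correlation of paired regional summary values (e.g. median regional
#' expression from two independent datasets), matched by region name. The
#' p-value uses the t approximation on `n - 2` degrees of freedom.
#'
#' @param profile_a,profile_b named numeric vectors; names are matched.
#' @return list with `estimate` (Spearman's r), `p.value`, `n`.
#' @export
profile_correlation <- function(profile_a, profile_b) {
  common <- intersect(names(profile_a), names(profile_b))
  if (length(common) < 3L) stop("need at least 3 matched regions")
  a <- profile_a[common]
  b <- profile_b[common]
  rs <- cor(a, b, method = "spearman")
  list(estimate = rs, p.value = .spearman_p(rs, length(common)),
       n = length(common))
}

# two-sided p for Spearman's r via the t approximation with n - 2 df
.spearman_p <- function(rs, n) {
  if (n < 3L || is.na(rs)) return(NA_real_)
  if (abs(rs) >= 1) return(0)
  tval <- rs * sqrt((n - 2) / (1 - rs^2))
  2 * pt(-abs(tval), df = n - 2)
}
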