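# Co-expression networks: donor-averaged Spearman correlation matrices,
# complete-linkage clustering, soft thresholding, topological overlap,
# module detection and hypergeometric gene-set enrichment.

#' Donor-averaged Spearman correlation matrix
#'
#' Computes, for each donor, the gene-by-gene Spearman correlation across
#' that donor's samples, then averages each cell over donors. A gene that is
#' constant within a donor yields NA for that donor's cells; those cells are
#' averaged over the remaining donors and flagged.
#'
#' @param donor_sample_sets list of `voxgex_donor_samples` (>= 1 donor, each
#'   with >= 3 samples).
#' @param gene_ids genes to include (>= 2; default: all genes of the first
#'   donor).
#' @return gene x gene matrix of averaged correlations (unit diagonal);
#'   attribute `"n_donors_used"` gives the per-cell donor count, and
#'   attribute `"flagged"` is TRUE if any cell lost a donor.
#' @export
donor_averaged_correlation <- function(donor_sample_sets, gene_ids = NULL) {
  if (inherits(donor_sample_sets, "voxgex_donor_samples"))
    donor_sample_sets <- list(donor_sample_sets)
  if (!length(donor_sample_sets)) stop("need at least one donor")
  if (is.null(gene_ids)) gene_ids <- donor_sample_sets[[1]]$gene_ids
  if (length(gene_ids) < 2L) stop("need at least 2 genes")
  g <- length(gene_ids)
  acc <- matrix(0, g, g, dimnames = list(gene_ids, gene_ids))
  cnt <- matrix(0L, g, g)
  for (d in donor_sample_sets) {
    stopifnot(inherits(d, "voxgex_donor_samples"))
    if (nrow(d$coords) < 3L) stop("each donor needs >= 3 samples")
    x <- d$expression[, gene_ids, drop = FALSE]
    cm <- suppressWarnings(cor(x, method = "spearman"))
    ok <- !is.na(cm)
    acc[ok] <- acc[ok] + cm[ok]
    cnt <- cnt + ok
  }
  if (any(cnt == 0L))
    stop("some gene pairs are constant in every donor; cannot average")
  out <- acc / cnt
  diag(out) <- 1
  attr(out, "n_donors_used") <- cnt
  attr(out, "flagged") <- any(cnt < length(donor_sample_sets))
  out
}

#' Complete-linkage clusters from a correlation matrix
#'
#' Agglomerative complete-linkage clustering on the dissimilarity
#' `1 - correlation`, cut into `k` groups.
#'
#' @param cor_matrix symmetric correlation matrix.
#' @param k number of clusters, `1 <= k <= n_genes`.
#' @return named integer vector of cluster labels.
#' @export
complete_linkage_clusters <- function(cor_matrix, k) {
  n <- nrow(cor_matrix)
  if (k < 1L || k > n) stop("k must be between 1 and the number of genes")
  hc <- hclust(as.dist(1 - cor_matrix), method = "complete")
  cutree(hc, k = k)
}

#' Rank of one correlation within a gene's library-wide correlations
#'
#' Ranks `cor(a, b)` within the set of correlations between gene `a` and
#' every other gene of the library, strongest first; ties share the better
#' (smaller) rank.
#'
#' @param gene_a,gene_b gene ids present in the matrix.
#' @param cor_matrix full library correlation matrix (>= 2 genes).
#' @return list with `r`, `rank`, `n` (competitor count) and `percentile`
#'   (`100 * rank / n`, so "top x percent").
#' @export
correlation_rank <- function(gene_a, gene_b, cor_matrix) {
  ids <- rownames(cor_matrix)
  if (!(gene_a %in% ids) || !(gene_b %in% ids))
    stop("gene absent from the correlation library")
  others <- setdiff(ids, gene_a)
  r_all <- cor_matrix[gene_a, others]
  r_ab <- cor_matrix[gene_a, gene_b]
  rk <- 1L + sum(r_all > r_ab)
  list(r = unname(r_ab), rank = rk, n = length(others),
       percentile = 100 * rk / length(others))
}

#' Select a soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power beta, forms the unsigned adjacency
#' `|cor|^beta`, computes node connectivities `k_i`, and fits
#' `log10(frequency)` against `log10(k)` over log-spaced connectivity bins.
#' The fit index R^2 is signed (multiplied by -1 when the slope is
#' positive, as a scale-free fit requires a decreasing frequency). The
#' selected beta is the smallest power with `R^2 >= r2_threshold`; if none
#' qualifies, the power maximising R^2 is returned with
#' `criterion_met = FALSE`.
#'
#' @param cor_matrix gene x gene correlation matrix.
#' @param candidate_powers positive powers to scan (default 1:20).
#' @param r2_threshold scale-free fit threshold (default 0.8).
#' @param n_bins number of log-spaced connectivity bins (default 10).
#' @return list with `beta`, `criterion_met`, and `fit_table` (data.frame:
#'   `power`, `r_squared`, `slope`, `mean_connectivity`, `degenerate`).
#' @export
select_soft_threshold <- function(cor_matrix, candidate_powers = 1:20,
                                  r2_threshold = 0.8, n_bins = 10) {
  if (!length(candidate_powers) || any(candidate_powers <= 0))
    stop("candidate_powers must be nonempty and positive")
  fit <- lapply(candidate_powers, function(beta) {
    a <- abs(cor_matrix)^beta
    diag(a) <- 0
    k <- rowSums(a)
    if (all(k == 0)) stop("all-zero adjacency at power ", beta)
    sf <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = beta, r_squared = sf$r_squared, slope = sf$slope,
               mean_connectivity = mean(k), degenerate = sf$degenerate)
  })
  fit_table <- do.call(rbind, fit)
  ok <- which(!fit_table$degenerate & fit_table$r_squared >= r2_threshold)
  if (length(ok)) {
    list(beta = fit_table$power[ok[1]], criterion_met = TRUE,
         fit_table = fit_table)
  } else {
    usable <- which(!fit_table$degenerate)
    if (!length(usable))
      return(list(beta = NA_real_, criterion_met = FALSE,
                  fit_table = fit_table))
    best <- usable[which.max(fit_table$r_squared[usable])]
    list(beta = fit_table$power[best], criterion_met = FALSE,
         fit_table = fit_table)
  }
}

#' Scale-free topology fit index of a connectivity vector
#'
#' Bins connectivities into `n_bins` log-spaced bins, regresses
#' `log10(frequency)` on `log10(mean bin connectivity)` over nonempty bins,
#' and signs R^2 by the slope direction. Fewer than 3 usable bins (e.g. all
#' connectivities equal) is reported as a degenerate non-fit.
#'
#' @param k nonnegative connectivity vector.
#' @param n_bins number of log-spaced bins.
#' @return list with `r_squared`, `slope`, `degenerate`.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3L || diff(range(k)) < .Machine$double.eps^0.5 * max(k))
    return(list(r_squared = NA_real_, slope = NA_real_, degenerate = TRUE))
  br <- 10^seq(log10(min(k)), log10(max(k)), length.out = n_bins + 1)
  br[1] <- br[1] * (1 - 1e-12)
  br[n_bins + 1] <- br[n_bins + 1] * (1 + 1e-12)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- vapply(seq_len(n_bins), function(b) {
    if (freq[b] == 0L) NA_real_ else mean(k[as.integer(bin) == b])
  }, numeric(1))
  use <- freq > 0L & !is.na(kmean) & kmean > 0
  if (sum(use) < 3L)
    return(list(r_squared = NA_real_, slope = NA_real_, degenerate = TRUE))
  x <- log10(kmean[use])
  y <- log10(freq[use] / sum(freq))
  f <- lm(y ~ x)
  sl <- unname(coef(f)[2])
  r2 <- summary(f)$r.squared
  list(r_squared = if (!is.na(sl) && sl > 0) -r2 else r2,
       slope = sl, degenerate = FALSE)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `l_ij = sum_u a_iu a_uj` and `k_i = sum_u a_iu`; the diagonal is set
#' to 1. High TOM means two genes are strongly connected and share
#' neighbours.
#'
#' @param adjacency symmetric matrix with entries in `[0, 1]` (the diagonal
#'   is ignored and treated as 0).
#' @return symmetric TOM with unit diagonal, entries in `[0, 1]`.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-10)
    stop("adjacency must be symmetric")
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1)
    stop("adjacency entries must lie in [0, 1]")
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut statically at `cut_height`; clusters smaller than `min_module_size`
#' are assigned to the background (module 0). Surviving modules are
#' relabelled 1, 2, ... by decreasing size. The default cut sits just below
#' 1 because the TOM dissimilarity between unrelated genes concentrates at
#' 1 in sparse (soft-thresholded) networks, while co-expressed genes merge
#' well below it.
#'
#' @param tom topological overlap matrix.
#' @param cut_height static tree-cut height in `(0, 1)` (default 0.95).
#' @param min_module_size smallest cluster kept as a module (default 5).
#' @return named integer vector of module labels (0 = background).
#' @export
detect_modules <- function(tom, cut_height = 0.95, min_module_size = 5L) {
  if (cut_height <= 0 || cut_height >= 1)
    stop("cut_height must be in (0, 1)")
  hc <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  out <- integer(length(raw))
  names(out) <- names(raw)
  if (length(keep)) {
    keep <- keep[order(-sizes[as.character(keep)], keep)]
    for (i in seq_along(keep)) out[raw == keep[i]] <- i
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Over-representation of a query gene set in each annotated set:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = |background|, K = |set|,
#' n = |query|)` and `k` the observed overlap. Adjustment across sets is
#' Bonferroni (e.g. across tissues) or Benjamini-Hochberg (e.g. across
#' gene-set collections).
#'
#' @param query_set character vector of gene ids (subset of background).
#' @param annotated_sets named list of character vectors (each a subset of
#'   background).
#' @param background character vector: the gene universe.
#' @param adjust "bonferroni" or "BH".
#' @return data.frame with one row per annotated set: `set_id`,
#'   `overlap_count`, `query_size`, `set_size`, `background_size`,
#'   `p_hypergeom`, `p_adjusted`.
#' @export
hypergeometric_enrichment <- function(query_set, annotated_sets, background,
                                      adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  background <- unique(background)
  query_set <- unique(query_set)
  if (!all(query_set %in% background))
    stop("query set is not contained in the background")
  N <- length(background)
  n <- length(query_set)
  rows <- lapply(names(annotated_sets), function(id) {
    s <- unique(annotated_sets[[id]])
    if (!all(s %in% background))
      stop("annotated set '", id, "' is not contained in the background")
    K <- length(s)
    k <- length(intersect(query_set, s))
    p <- if (k == 0L) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap_count = k, query_size = n, set_size = K,
               background_size = N, p_hypergeom = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_hypergeom, method = adjust)
  out
}

#' Tissue differential-expression gene sets from a statistics table
#'
#' Utility mirroring how tissue-specific gene sets are defined from a
#' tissue-by-gene differential expression table: a gene belongs to a
#' tissue's set when its adjusted p-value is below `p_threshold` and its
#' absolute log fold change is at least `lfc_threshold`.
#'
#' @param de_table data.frame with columns `tissue`, `gene`, `p_adj`,
#'   `log_fc`.
#' @param p_threshold adjusted p-value cutoff (default 0.05).
#' @param lfc_threshold absolute log fold change cutoff (default 0.58).
#' @return named list of character vectors, one per tissue.
#' @export
filter_tissue_de <- function(de_table, p_threshold = 0.05,
                             lfc_threshold = 0.58) {
  need <- c("tissue", "gene", "p_adj", "log_fc")
  if (!all(need %in% names(de_table)))
    stop("de_table needs columns: ", paste(need, collapse = ", "))
  keep <- de_table$p_adj < p_threshold & abs(de_table$log_fc) >= lfc_threshold
  split(de_table$gene[keep], factor(de_table$tissue[keep],
                                    levels = unique(de_table$tissue)))
}

#' Select one probe per gene by differential stability
#'
#' Where several probes measure the same gene, keeps the probe with the
#' highest differential stability (ties go to the first listed probe).
#'
#' @param probe_table data.frame with columns `gene`, `probe`, `ds`.
#' @return data.frame with one row per gene.
#' @export
select_probe_by_stability <- function(probe_table) {
  need <- c("gene", "probe", "ds")
  if (!all(need %in% names(probe_table)))
    stop("probe_table needs columns: ", paste(need, collapse = ", "))
  picked <- lapply(split(seq_len(nrow(probe_table)), probe_table$gene),
                   function(ix) ix[which.max(probe_table$ds[ix])])
  out <- probe_table[unlist(picked), , drop = FALSE]
  out[order(out$gene), , drop = FALSE]
}
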