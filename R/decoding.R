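# Reverse-inference decoding: correlate expression maps with a library of
# meta-analytic term association maps; rank specificity; social vs
# non-social permutation contrast.

# gene values over the mask voxels, from any supported volume object
.mask_values <- function(gene_volume, mask) {
  if (inherits(gene_volume, "voxgex_expression_volume"))
    gene_volume <- gene_volume$values
  if (is.array(gene_volume) && length(dim(gene_volume)) == 3L) {
    if (!identical(dim(gene_volume), dim(mask)))
      stop("volume grid does not match the mask")
    return(gene_volume[mask])
  }
  stop("gene_volume must be an expression volume or 3D array")
}

#' Decode cognitive-state correlates of an expression map
#'
#' Spearman correlation, over mask voxels, between a gene's expression
#' volume and each term's association Z map; the strongest `top_k` terms
#' are reported. Correlations are invariant to monotone transforms of
#' either map.
#'
#' @param gene_volume a `voxgex_expression_volume` or 3D array.
#' @param term_maps named list of `voxgex_term_map`.
#' @param mask logical 3D array or `voxgex_atlas`.
#' @param top_k number of strongest terms to report (default 5).
#' @return list with `table` (data.frame: `term`, `r`, `rank`, sorted by
#'   descending r) and `top_terms` (character vector of length `top_k`).
#' @export
decode_gene <- function(gene_volume, term_maps, mask, top_k = 5L) {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  if (!length(term_maps)) stop("need at least one term map")
  g <- .mask_values(gene_volume, mask)
  if (sd(g) == 0)
    stop("constant gene volume: correlations are undefined")
  rg <- rank(g)
  r <- vapply(term_maps, function(tmap) {
    z <- tmap$z
    if (!identical(dim(z), dim(mask)))
      stop("term map grid does not match the mask")
    cor(rg, rank(z[mask]))
  }, numeric(1))
  ord <- order(r, decreasing = TRUE)
  tab <- data.frame(term = names(term_maps)[ord], r = unname(r[ord]),
                    rank = seq_along(r), stringsAsFactors = FALSE)
  list(table = tab, top_terms = head(tab$term, top_k))
}

#' Rank a gene's term correlation against the whole library
#'
#' Correlates every library gene's map with one term's Z map and ranks the
#' requested gene, strongest first; ties share the better rank.
#'
#' @param term_map a `voxgex_term_map`.
#' @param gene_library a `voxgex_volume_set` (typically the donor-averaged
#'   set), providing all library genes' mask-voxel values.
#' @param gene_id gene whose rank is requested.
#' @param mask logical 3D array or `voxgex_atlas`.
#' @return list with `r` (the gene's correlation), `rank`, `n_genes`,
#'   `percentile` (`100 * rank / n_genes`) and `all_r` (named vector).
#' @export
gene_rank_for_term <- function(term_map, gene_library, gene_id, mask) {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  stopifnot(inherits(gene_library, "voxgex_volume_set"))
  if (!gene_id %in% gene_library$gene_ids)
    stop("gene absent from the library: ", gene_id)
  if (!identical(dim(term_map$z), dim(mask)))
    stop("term map grid does not match the mask")
  mask_idx <- which(mask)
  if (!identical(mask_idx, gene_library$mask_idx))
    stop("library mask does not match")
  z <- rank(term_map$z[mask_idx])
  V <- gene_library$values
  R <- apply(V, 2, rank)
  r_all <- suppressWarnings(as.numeric(cor(z, R, method = "pearson")))
  names(r_all) <- gene_library$gene_ids
  r_g <- r_all[gene_id]
  rk <- 1L + sum(r_all > r_g, na.rm = TRUE)
  list(r = unname(r_g), rank = rk, n_genes = length(r_all),
       percentile = 100 * rk / length(r_all), all_r = r_all)
}

# Welch t statistic (two-sided use); returns NA when undefined
.welch_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(se2)
}

#' Social vs non-social permutation contrast of an expression map
#'
#' Each term is scored as the median of the gene's expression over the
#' term's suprathreshold voxels (association-map FDR p below
#' `q_threshold`); terms with no suprathreshold voxel are excluded and
#' reported. The observed statistic is the Welch t between social and
#' non-social term scores; its p-value comes from randomly reassigning the
#' category labels to terms (`n_perm` permutations, add-one smoothing, so
#' the p-value is never 0).
#'
#' @param gene_volume a `voxgex_expression_volume` or 3D array.
#' @param term_maps named list of `voxgex_term_map`.
#' @param categories named character vector `term -> category` with values
#'   "social" / "non-social" (terms absent or with other values are
#'   ignored); defaults to the categories carried by the maps.
#' @param mask logical 3D array or `voxgex_atlas`.
#' @param q_threshold FDR threshold defining suprathreshold voxels
#'   (default 0.05).
#' @param n_perm number of label permutations (default 5000).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `voxgex_social_contrast`: list with `scores`
#'   (data.frame: `term`, `category`, `n_voxels`, `score`), `mean_social`,
#'   `mean_nonsocial`, `t`, `p_perm`, `n_perm`, `seed`,
#'   `excluded_terms`.
#' @export
social_contrast <- function(gene_volume, term_maps, categories = NULL,
                            mask, q_threshold = 0.05, n_perm = 5000L,
                            seed = 1L) {
  if (inherits(mask, "voxgex_atlas")) mask <- mask$mask
  g <- .mask_values(gene_volume, mask)
  if (is.null(categories)) {
    categories <- vapply(term_maps, function(tm) tm$category, character(1))
    names(categories) <- names(term_maps)
  }
  categories <- categories[categories %in% c("social", "non-social")]
  use <- intersect(names(term_maps), names(categories))
  if (length(use) < 4L)
    stop("need labelled terms in both categories (>= 2 each)")

  excluded <- character(0)
  rows <- lapply(use, function(tm) {
    map <- term_maps[[tm]]
    supra <- map$p_fdr[mask] < q_threshold
    supra[is.na(supra)] <- FALSE
    if (!any(supra)) {
      excluded <<- c(excluded, tm)
      return(NULL)
    }
    data.frame(term = tm, category = unname(categories[tm]),
               n_voxels = sum(supra), score = median(g[supra]),
               stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, rows)
  if (is.null(scores) || length(unique(scores$category)) < 2L ||
      min(table(scores$category)) < 2L)
    stop("need >= 2 scored terms per category")

  is_social <- scores$category == "social"
  t_obs <- .welch_t(scores$score[is_social], scores$score[!is_social])
  n_social <- sum(is_social)
  n_terms <- nrow(scores)
  t_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n_terms, n_social)
      .welch_t(scores$score[idx], scores$score[-idx])
    }, numeric(1))
  })
  p_perm <- (1 + sum(abs(t_perm) >= abs(t_obs), na.rm = TRUE)) / (n_perm + 1)

  structure(
    list(scores = scores,
         mean_social = mean(scores$score[is_social]),
         mean_nonsocial = mean(scores$score[!is_social]),
         t = t_obs, p_perm = p_perm, n_perm = as.integer(n_perm),
         seed = as.integer(seed), excluded_terms = excluded),
    class = "voxgex_social_contrast"
  )
}

#' @export
print.voxgex_social_contrast <- function(x, ...) {
  cat("voxgex_social_contrast: t =", format(x$t, digits = 4),
      ", p_perm =", format(x$p_perm, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
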