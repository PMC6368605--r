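#!/usr/bin/env Rscript
# Stage 6: reverse-inference decoding of the target gene's map.
#
# Spearman correlation of the donor-averaged map with every term
# association map, the gene's library rank for its best term, and the
# social vs non-social permutation contrast of median expression over each
# term's FDR-suprathreshold voxels.

library(voxgex)

pipe <- readRDS("results/cache/pipeline.rds")
atlas <- pipe$atlas
dir.create("results/decoding", recursive = TRUE, showWarnings = FALSE)

dec <- pipe$decoding
utils::write.table(dec$table, "results/decoding/term_correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%s: top decoded terms: %s\n", pipe$target_gene,
            paste(dec$top_terms, collapse = ", ")))
planted <- names(pipe$ground_truth$term_gene_links)[
  pipe$ground_truth$term_gene_links == pipe$target_gene]
cat(sprintf("Planted term %s decoded at rank %d (r = %.3f)\n", planted[1],
            which(dec$table$term == planted[1]),
            dec$table$r[dec$table$term == planted[1]]))

# library rank of the target gene for its top term
grk <- gene_rank_for_term(pipe$term_maps[[dec$top_terms[1]]], pipe$average,
                          pipe$target_gene, atlas)
cat(sprintf("Rank of %s for %s across the %d-gene library: %d (top %.1f%%)\n",
            pipe$target_gene, dec$top_terms[1], grk$n_genes, grk$rank,
            grk$percentile))

sc <- pipe$social_contrast
cat(sprintf("Social vs non-social contrast: t = %.2f, mean social %.3f vs non-social %.3f, p_perm = %.4g (%d permutations, seed %d)\n",
            sc$t, sc$mean_social, sc$mean_nonsocial, sc$p_perm, sc$n_perm,
            sc$seed))
if (length(sc$excluded_terms))
  cat("Excluded terms (no suprathreshold voxels):",
      paste(sc$excluded_terms, collapse = ", "), "\n")

utils::write.table(sc$scores, "results/decoding/term_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(top_terms = dec$top_terms,
       gene_rank = grk[c("r", "rank", "n_genes", "percentile")],
       social_contrast = list(t = sc$t, p_perm = sc$p_perm,
                              n_perm = sc$n_perm, seed = sc$seed,
                              mean_social = sc$mean_social,
                              mean_nonsocial = sc$mean_nonsocial)),
  "results/decoding/summary.json", auto_unbox = TRUE, digits = NA)
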