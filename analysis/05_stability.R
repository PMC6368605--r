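#!/usr/bin/env Rscript
# Stage 5: donor-to-donor reproducibility (differential stability).
#
# Voxel-level DS for every gene (Spearman correlation of each donor pair's
# dense maps, averaged over the 15 pairs), with per-pair p-values computed
# at the smaller donor's sample count, plus the library-wide decile of the
# target gene.

library(voxgex)

pipe <- readRDS("results/cache/pipeline.rds")
dir.create("results/stability", recursive = TRUE, showWarnings = FALSE)

n_samples <- stats::setNames(
  vapply(pipe$donors, function(d) nrow(d$coords), integer(1)),
  vapply(pipe$donors, `[[`, "", "donor_id"))

# rank each donor's maps once, then correlate pairs per gene
ranked <- lapply(pipe$volumes, function(v) scale(apply(v$values, 2, rank)))
pairs <- utils::combn(length(ranked), 2)
n_vox <- nrow(ranked[[1]])
pair_r <- sapply(seq_len(ncol(pairs)), function(q)
  colSums(ranked[[pairs[1, q]]] * ranked[[pairs[2, q]]]) / (n_vox - 1))
ds_all <- rowMeans(pair_r)
deciles <- vapply(ds_all, decile_rank, integer(1),
                  library_ds_values = ds_all)

tab <- data.frame(gene = pipe$volumes[[1]]$gene_ids, ds = ds_all,
                  decile = deciles,
                  module = pipe$ground_truth$module_assignment)
utils::write.table(tab[order(-tab$ds), ], "results/stability/ds_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("Voxel-level DS over %d genes: median %.3f (IQR %.3f-%.3f)\n",
            nrow(tab), median(tab$ds), quantile(tab$ds, 0.25),
            quantile(tab$ds, 0.75)))

target <- pipe$stability
cat(sprintf("%s: DS = %.3f over %d pairs, library decile %d\n",
            target$gene_id, ds_all[pipe$target_gene],
            ncol(pair_r), deciles[pipe$target_gene]))
cat("Per-pair detail for the target gene (voxel units):\n")
print(utils::head(target$pairs[order(-target$pairs$r), ], 5),
      row.names = FALSE)
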