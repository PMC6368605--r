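#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Builds the shared parcellation atlas, a gene library with planted
# co-expression modules, six donors' scattered sample sets, and a library
# of term association maps whose "social" terms are planted on the target
# gene's high-expression regions. Everything downstream (stages 02-06)
# reads the cached pipeline object this stage writes.

library(voxgex)

seed <- 1L
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cat("Running the synthetic pipeline at the default study scale...\n")
pipe <- run_pipeline(seed = seed, n_perm = 5000L)
saveRDS(pipe, "results/cache/pipeline.rds")

atlas <- pipe$atlas
cat(sprintf("Atlas: %s grid, %d mask voxels, %d regions\n",
            paste(atlas$grid_shape, collapse = "x"), sum(atlas$mask),
            length(atlas$region_names)))
write_atlas(atlas, "results/data/atlas")

for (d in pipe$donors) {
  write_samples_tsv(d, sprintf("results/data/samples_%s.tsv", d$donor_id))
  cat(sprintf("  %s: %d samples\n", d$donor_id, nrow(d$coords)))
}

gt <- pipe$ground_truth
jsonlite::write_json(
  list(module_assignment = as.list(gt$module_assignment),
       term_gene_links = as.list(gt$term_gene_links),
       rng_seed = gt$rng_seed),
  "results/data/ground_truth.json", auto_unbox = TRUE, digits = NA)

dir.create("results/data/terms", showWarnings = FALSE)
invisible(lapply(pipe$term_maps, write_term_map, dir = "results/data/terms"))
utils::write.table(
  data.frame(term = names(pipe$categories), category = pipe$categories),
  "results/data/term_categories.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

cat(sprintf("Wrote %d donors, %d genes, %d term maps under results/data/\n",
            length(pipe$donors), ncol(pipe$donors[[1]]$expression),
            length(pipe$term_maps)))
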