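# End-to-end synthetic pipeline driver used by the analysis scripts and the
# acceptance checks.

#' Default synthetic study configuration
#'
#' Desk-scale but structurally faithful defaults: a 20^3 grid with 54
#' regions (mirroring a 54-region left-hemisphere parcellation), 200 genes
#' with 4 planted 10-gene modules, 6 donors sampled at 363-946 scattered
#' locations each, and a 20-term association-map library half of whose
#' terms are linked to genes.
#'
#' @return named list of generator parameters.
#' @export
default_config <- function() {
  list(
    grid_shape = c(20L, 20L, 20L),
    n_regions = 54L,
    n_genes = 200L,
    n_modules = 4L,
    module_size = 10L,
    within_module_cor = 0.9,
    profile_noise_sd = 1,
    measurement_noise_sd = 0.5,
    n_donors = 6L,
    samples_range = c(363L, 946L),
    n_terms = 20L,
    active_fraction = 0.1,
    z_effect = 4
  )
}

#' Run the full synthetic pipeline
#'
#' Generates an atlas, gene library, donors and term maps from one seed,
#' then runs every stage: dense per-donor volumes and their average,
#' regional enrichment for a target gene, donor-averaged co-expression with
#' module detection, differential stability, and decoding with the
#' social/non-social contrast.
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param config parameter list as from [default_config()] (entries may be
#'   overridden).
#' @param target_gene gene to decode and score (default: first member of
#'   the first planted module).
#' @param n_perm permutations for the social contrast.
#' @return list with all intermediate and final objects.
#' @export
run_pipeline <- function(seed = 1L, config = default_config(),
                         target_gene = NULL, n_perm = 1000L) {
  cfg <- utils::modifyList(default_config(), config)
  seed <- as.integer(seed)

  atlas <- make_atlas(cfg$grid_shape, cfg$n_regions, seed = seed)
  lib <- simulate_gene_library(
    atlas, cfg$n_genes, cfg$n_modules, cfg$module_size,
    within_module_cor = cfg$within_module_cor,
    noise_sd = cfg$profile_noise_sd, seed = seed + 1L)
  gt <- lib$ground_truth
  if (is.null(target_gene))
    target_gene <- names(gt$module_assignment)[gt$module_assignment == 1L][1]

  n_samples <- withr::with_seed(seed + 2L, {
    sample(seq(cfg$samples_range[1], cfg$samples_range[2]), cfg$n_donors,
           replace = TRUE)
  })
  donors <- lapply(seq_len(cfg$n_donors), function(d) {
    sample_donor(atlas, gt$regional_profiles, n_samples[d],
                 measurement_noise_sd = cfg$measurement_noise_sd,
                 seed = seed + 10L + d, donor_id = sprintf("donor_%d", d))
  })

  volumes <- lapply(donors, build_expression_volumes, atlas = atlas)
  avg <- average_volumes(volumes)

  # term maps: "social" terms are linked to genes of the target gene's
  # module (so their active regions overlap its high-expression regions,
  # the first forced to the target gene itself); "non-social" terms are
  # linked to background genes; the rest stay unlinked and unlabelled
  module_genes <- names(gt$module_assignment)[
    gt$module_assignment == gt$module_assignment[target_gene]]
  n_social <- max(2L, cfg$n_terms %/% 4L)
  link_genes <- withr::with_seed(seed + 3L, {
    soc <- c(target_gene,
             sample(setdiff(module_genes, target_gene), n_social - 1L))
    bg_pool <- names(gt$module_assignment)[gt$module_assignment == 0L]
    c(soc, sample(bg_pool, n_social))
  })
  links <- stats::setNames(link_genes,
                           sprintf("term_%02d", seq_len(2L * n_social)))
  tm <- simulate_term_maps(atlas, gt, cfg$n_terms,
                           active_fraction = cfg$active_fraction,
                           z_effect = cfg$z_effect, seed = seed + 4L,
                           links = links)
  gt <- tm$ground_truth
  categories <- stats::setNames(
    rep(c("social", "non-social"), each = n_social), names(links))

  rm_mat <- region_means(volumes, atlas, target_gene, mode = "voxel")
  enrich <- region_enrichment(rm_mat)

  cor_mat <- donor_averaged_correlation(donors)
  sft <- select_soft_threshold(cor_mat)
  # fall back to the conventional unsigned-network power when the
  # scale-free criterion is not met (planted-module libraries need not be
  # scale-free)
  beta <- if (sft$criterion_met) sft$beta else 6
  adj <- abs(cor_mat)^beta
  diag(adj) <- 0
  tom <- tom_similarity(adj)
  modules <- detect_modules(tom)

  # voxel-level DS on the donors' dense maps (the pipeline default)
  ds_profiles <- sapply(volumes, function(v) v$values[, target_gene])
  colnames(ds_profiles) <- vapply(donors, `[[`, "", "donor_id")
  ds <- differential_stability(ds_profiles, gene_id = target_gene,
                               sample_sizes = stats::setNames(
                                 n_samples, colnames(ds_profiles)))

  decoding <- decode_gene(get_volume(avg, target_gene), tm$maps, atlas)
  contrast <- social_contrast(get_volume(avg, target_gene), tm$maps,
                              categories = categories, mask = atlas,
                              n_perm = n_perm, seed = seed + 5L)

  list(seed = seed, config = cfg, atlas = atlas, ground_truth = gt,
       donors = donors, volumes = volumes, average = avg,
       target_gene = target_gene, term_maps = tm$maps,
       categories = categories, region_means = rm_mat,
       enrichment = enrich, cor_matrix = cor_mat, soft_threshold = sft,
       tom = tom, modules = modules, stability = ds,
       decoding = decoding, social_contrast = contrast)
}
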