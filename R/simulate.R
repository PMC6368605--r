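#' Simulate a gene library with planted co-expression modules
#'
#' Generates per-gene regional expression profiles over the atlas regions.
#' Genes in a planted module share a latent regional profile: a member's
#' profile is `baseline + lambda * L_m + noise_sd * eps`, with `L_m` the
#' module's latent standard-normal profile, `eps` independent standard-normal
#' noise and `lambda = noise_sd * sqrt(rho / (1 - rho))`, so that the expected
#' correlation between two members' profiles is `rho = within_module_cor`.
#' Background genes get independent profiles with the same marginal variance.
#'
#' @param atlas a `voxgex_atlas`.
#' @param n_genes total number of genes.
#' @param n_modules number of planted modules.
#' @param module_size genes per module; `n_modules * module_size <= n_genes`.
#' @param within_module_cor target correlation of module members' regional
#'   profiles, in `[0, 1]`.
#' @param noise_sd standard deviation of the per-gene profile noise; must be
#'   positive unless `within_module_cor = 1` is requested (in which case it
#'   must be 0 and members coincide with the latent profile).
#' @param seed integer seed; the library is a pure function of it.
#' @param baseline additive offset of all profiles (arbitrary expression
#'   units), giving profiles a realistic positive location.
#'
#' @return A list with `ground_truth` (class `voxgex_ground_truth`: fields
#'   `regional_profiles`, `module_assignment`, `term_gene_links`, `rng_seed`)
#'   and `regional_profiles` (gene x region matrix, also inside the ground
#'   truth).
#' @export
simulate_gene_library <- function(atlas, n_genes, n_modules, module_size,
                                  within_module_cor = 0.9, noise_sd = 1,
                                  seed = 1L, baseline = 5) {
  stopifnot(inherits(atlas, "voxgex_atlas"))
  n_genes <- as.integer(n_genes)
  n_modules <- as.integer(n_modules)
  module_size <- as.integer(module_size)
  rho <- within_module_cor
  if (n_modules * module_size > n_genes)
    stop("n_modules * module_size exceeds n_genes")
  if (n_modules > 0L && module_size < 3L)
    stop("each planted module needs >= 3 member genes")
  if (rho < 0 || rho > 1) stop("within_module_cor must be in [0, 1]")
  if (rho < 1 && noise_sd <= 0)
    stop("noise_sd must be positive unless within_module_cor = 1")
  if (rho == 1 && noise_sd != 0)
    stop("within_module_cor = 1 requires noise_sd = 0")

  n_regions <- length(atlas$region_names)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  lambda <- if (rho == 1) 1 else noise_sd * sqrt(rho / (1 - rho))
  marg_sd <- sqrt(lambda^2 + noise_sd^2)

  module_assignment <- integer(n_genes)
  names(module_assignment) <- gene_ids
  profiles <- withr::with_seed(seed, {
    P <- matrix(0, n_genes, n_regions,
                dimnames = list(gene_ids, atlas$region_names))
    g <- 0L
    if (n_modules > 0L) {
      for (m in seq_len(n_modules)) {
        latent <- rnorm(n_regions)
        for (s in seq_len(module_size)) {
          g <- g + 1L
          module_assignment[g] <- m
          P[g, ] <- baseline + lambda * latent + noise_sd * rnorm(n_regions)
        }
      }
    }
    if (g < n_genes)
      P[(g + 1L):n_genes, ] <- baseline +
        marg_sd * matrix(rnorm((n_genes - g) * n_regions), n_genes - g)
    P
  })

  gt <- structure(
    list(
      regional_profiles = profiles,
      module_assignment = module_assignment,
      term_gene_links = character(0),
      rng_seed = as.integer(seed)
    ),
    class = "voxgex_ground_truth"
  )
  list(ground_truth = gt, regional_profiles = profiles)
}

#' Simulate one donor's scattered brain samples
#'
#' Draws sample locations uniformly over the mask voxels without replacement,
#' adds a sub-voxel coordinate jitter (emulating residual misregistration
#' after donors are brought into a common template space), and sets each
#' sample's expression to its region's true profile value plus Gaussian
#' measurement noise.
#'
#' @param atlas a `voxgex_atlas`.
#' @param regional_profiles gene x region matrix of true mean expression.
#' @param n_samples number of samples (>= 4, at most the mask voxel count).
#' @param measurement_noise_sd standard deviation of the additive Gaussian
#'   measurement noise (0 reproduces the regional truth exactly).
#' @param seed integer seed; the sample set is a pure function of it.
#' @param donor_id donor identifier string.
#' @param coord_jitter half-width of the uniform coordinate jitter in voxels
#'   (< 0.5 so that rounding recovers the sampled voxel).
#'
#' @return An object of class `voxgex_donor_samples`: a list with `donor_id`,
#'   `coords` (n x 3 continuous 0-based voxel coordinates), `expression`
#'   (n x gene matrix) and `gene_ids`.
#' @export
sample_donor <- function(atlas, regional_profiles, n_samples,
                         measurement_noise_sd = 0.5, seed = 1L,
                         donor_id = "donor", coord_jitter = 0.45) {
  stopifnot(inherits(atlas, "voxgex_atlas"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (coord_jitter < 0 || coord_jitter >= 0.5)
    stop("coord_jitter must be in [0, 0.5)")
  vox <- mask_coords(atlas)
  if (n_samples > nrow(vox))
    stop("n_samples (", n_samples, ") exceeds the mask voxel count (",
         nrow(vox), ")")

  out <- withr::with_seed(seed, {
    pick <- sample.int(nrow(vox), n_samples)
    base <- vox[pick, , drop = FALSE]
    coords <- base + matrix(runif(3 * n_samples, -coord_jitter, coord_jitter),
                            n_samples, 3)
    region <- region_at(base, atlas)
    expr <- t(regional_profiles[, region, drop = FALSE])
    if (measurement_noise_sd > 0)
      expr <- expr + matrix(rnorm(length(expr), 0, measurement_noise_sd),
                            nrow(expr))
    list(coords = coords, expr = expr)
  })
  dimnames(out$expr) <- list(NULL, rownames(regional_profiles))
  colnames(out$coords) <- c("x", "y", "z")

  structure(
    list(
      donor_id = donor_id,
      coords = out$coords,
      expression = out$expr,
      gene_ids = rownames(regional_profiles)
    ),
    class = "voxgex_donor_samples"
  )
}

#' @export
print.voxgex_donor_samples <- function(x, ...) {
  cat("voxgex_donor_samples:", x$donor_id, "-", nrow(x$coords), "samples,",
      length(x$gene_ids), "genes\n")
  invisible(x)
}

#' Simulate a library of term association maps
#'
#' Emulates a meta-analytic decoding library: each term gets an association
#' Z volume and a matching FDR p volume on the atlas grid. For a term linked
#' to a gene, the active voxel set is placed inside that gene's
#' highest-expression regions; unlinked terms get spatially random active
#' sets. Z values are `Normal(z_effect, 1)` in active voxels and
#' `Normal(0, 1)` elsewhere; the FDR p volume applies Benjamini-Hochberg to
#' two-sided normal p-values over the mask voxels.
#'
#' @param atlas a `voxgex_atlas`.
#' @param ground_truth a `voxgex_ground_truth` (provides regional profiles
#'   and records the created term-gene links).
#' @param n_terms number of terms.
#' @param active_fraction fraction of mask voxels active per term, in (0, 1).
#' @param z_effect mean Z in active voxels (> 0, or 0 for a pure null
#'   library).
#' @param seed integer seed; the maps are a pure function of it.
#' @param links named character vector `term -> gene_id` for linked terms;
#'   by default the first `floor(n_terms / 2)` terms are linked to distinct
#'   randomly chosen genes. Terms not named are unlinked.
#' @param categories optional named character vector `term -> category`
#'   (e.g. "social" / "non-social") copied onto the maps.
#'
#' @return A list with `maps` (named list of `voxgex_term_map`: fields
#'   `term`, `z` (3D array, NA outside mask), `p_fdr` (3D array), `category`,
#'   `active` (logical 3D array of the planted active set)) and
#'   `ground_truth` (the input with `term_gene_links` filled in).
#' @export
simulate_term_maps <- function(atlas, ground_truth, n_terms,
                               active_fraction = 0.1, z_effect = 4,
                               seed = 1L, links = NULL, categories = NULL) {
  stopifnot(inherits(atlas, "voxgex_atlas"),
            inherits(ground_truth, "voxgex_ground_truth"))
  if (active_fraction <= 0 || active_fraction >= 1)
    stop("active_fraction must be in (0, 1)")
  if (z_effect < 0) stop("z_effect must be >= 0")
  n_terms <- as.integer(n_terms)
  profiles <- ground_truth$regional_profiles
  gene_ids <- rownames(profiles)
  terms <- sprintf("term_%02d", seq_len(n_terms))

  mask_idx <- which(atlas$mask)
  n_mask <- length(mask_idx)
  n_active <- max(1L, round(active_fraction * n_mask))
  lab_vec <- atlas$labels[mask_idx]

  maps <- withr::with_seed(seed, {
    if (is.null(links)) {
      n_link <- n_terms %/% 2L
      links <- if (n_link > 0L)
        stats::setNames(sample(gene_ids, n_link), terms[seq_len(n_link)])
      else character(0)
    }
    if (length(links) && !all(links %in% gene_ids))
      stop("term linked to a gene absent from the ground truth: ",
           paste(setdiff(links, gene_ids), collapse = ", "))
    if (length(links) && !all(names(links) %in% terms))
      stop("link names must be term ids")

    lapply(terms, function(tm) {
      if (tm %in% names(links)) {
        gene <- links[[tm]]
        # fill whole top-expression regions of the linked gene, then a random
        # subset of the last region reached
        ord <- order(profiles[gene, ], decreasing = TRUE)
        full <- integer(0)
        for (r in ord) {
          rv <- which(lab_vec == r)
          if (length(full) + length(rv) <= n_active) {
            full <- c(full, rv)
            if (length(full) == n_active) break
          } else {
            need <- n_active - length(full)
            full <- c(full, sample(rv, need))
            break
          }
        }
        active_pos <- sort(full)
      } else {
        active_pos <- sort(sample.int(n_mask, n_active))
      }
      z <- rnorm(n_mask)
      z[active_pos] <- z[active_pos] + z_effect
      p <- 2 * pnorm(-abs(z))
      p_fdr <- p.adjust(p, method = "BH")

      zv <- array(NA_real_, dim = atlas$grid_shape)
      pv <- array(NA_real_, dim = atlas$grid_shape)
      av <- array(FALSE, dim = atlas$grid_shape)
      zv[mask_idx] <- z
      pv[mask_idx] <- p_fdr
      av[mask_idx[active_pos]] <- TRUE
      structure(
        list(term = tm, z = zv, p_fdr = pv,
             category = if (!is.null(categories) && tm %in% names(categories))
               categories[[tm]] else NA_character_,
             active = av),
        class = "voxgex_term_map"
      )
    })
  })
  names(maps) <- terms
  ground_truth$term_gene_links <- links
  list(maps = maps, ground_truth = ground_truth)
}
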