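test_that("donor-averaged correlation is monotone-invariant and recovers structure", {
  atlas <- small_atlas(n_regions = 54L)
  lib <- simulate_gene_library(atlas, 12, 2, 4, within_module_cor = 0.9,
                               noise_sd = 1, seed = 101)
  donors <- lapply(1:3, function(i)
    sample_donor(atlas, lib$regional_profiles, 300, seed = 110 + i,
                 donor_id = paste0("d", i)))

  # duplicating a gene under a monotone transform gives r = 1 in every donor
  dd <- donors[[1]]
  dd$expression <- cbind(dd$expression, g_dup = exp(dd$expression[, 1] / 2))
  dd$gene_ids <- colnames(dd$expression)
  cm1 <- donor_averaged_correlation(list(dd))
  expect_equal(cm1["gene_0001", "g_dup"], 1, tolerance = 1e-12)

  # planted modules: within-module cells exceed between-module cells
  cm <- donor_averaged_correlation(donors)
  mod <- lib$ground_truth$module_assignment
  within <- c(cm[mod == 1, mod == 1][upper.tri(cm[mod == 1, mod == 1])],
              cm[mod == 2, mod == 2][upper.tri(cm[mod == 2, mod == 2])])
  between <- as.numeric(cm[mod == 1, mod == 2])
  expect_gt(min(within), max(between))
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == 1))
})

test_that("independent genes stay near zero correlation with many samples", {
  # flat regional truth + iid measurement noise: genes share no structure,
  # so 500 samples bound the null Spearman correlation tightly
  atlas <- small_atlas(n_regions = 54L)
  flat <- matrix(5, 6, 54,
                 dimnames = list(sprintf("gene_%04d", 1:6),
                                 atlas$region_names))
  hits <- vapply(seq_len(40), function(r) {
    d <- sample_donor(atlas, flat, 500, measurement_noise_sd = 1,
                      seed = 300 + r)
    cm <- donor_averaged_correlation(list(d))
    max(abs(cm[upper.tri(cm)])) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("constant genes within a donor are averaged over the remaining donors", {
  atlas <- small_atlas(n_regions = 10L)
  lib <- simulate_gene_library(atlas, 4, 0, 0, seed = 104)
  d1 <- sample_donor(atlas, lib$regional_profiles, 50, seed = 105,
                     donor_id = "d1")
  d2 <- sample_donor(atlas, lib$regional_profiles, 50, seed = 106,
                     donor_id = "d2")
  d1$expression[, 2] <- 7  # constant in donor 1 only
  cm <- donor_averaged_correlation(list(d1, d2))
  cm2 <- donor_averaged_correlation(list(d2))
  expect_equal(cm["gene_0001", "gene_0002"], cm2["gene_0001", "gene_0002"],
               tolerance = 1e-12)
  expect_true(attr(cm, "flagged"))
})

test_that("complete linkage matches a brute-force agglomeration oracle", {
  # block-diagonal case: two perfect blocks are recovered at k = 2
  blocks <- matrix(0.05, 8, 8)
  blocks[1:4, 1:4] <- 0.99
  blocks[5:8, 5:8] <- 0.99
  diag(blocks) <- 1
  dimnames(blocks) <- list(paste0("g", 1:8), paste0("g", 1:8))
  lab <- complete_linkage_clusters(blocks, 2)
  expect_true(same_partition(lab, rep(1:2, each = 4)))

  # k = n gives singletons; k > n errors
  expect_identical(length(unique(complete_linkage_clusters(blocks, 8))), 8L)
  expect_error(complete_linkage_clusters(blocks, 9), "between 1")

  # random matrices vs the oracle at several cuts
  withr::with_seed(121, {
    for (trial in 1:5) {
      x <- matrix(rnorm(8 * 20), 20, 8)
      cm <- cor(x)
      D <- 1 - cm
      for (k in c(2, 3, 4)) {
        mine <- complete_linkage_clusters(cm, k)
        oracle <- linkage_oracle(D, k, "complete")
        expect_true(same_partition(mine, oracle))
      }
    }
  })
})

test_that("correlation rank uses descending order with best-rank ties", {
  withr::with_seed(131, {
    x <- matrix(rnorm(50 * 30), 30, 50,
                dimnames = list(NULL, sprintf("g%02d", 1:50)))
  })
  cm <- cor(x, method = "spearman")
  # brute-force sort oracle for a specific pair
  r_all <- cm["g01", setdiff(colnames(cm), "g01")]
  for (b in c("g02", "g17", "g50")) {
    res <- correlation_rank("g01", b, cm)
    expect_identical(res$rank,
                     as.integer(which(names(sort(r_all, decreasing = TRUE)) == b)))
    expect_equal(res$percentile, 100 * res$rank / 49)
  }

  # strongest correlate in a 100-gene library is "top 1%"
  best <- names(which.max(r_all))
  expect_identical(correlation_rank("g01", best, cm)$rank, 1L)

  # all-equal correlations share rank 1 (the better rank)
  eq <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(eq) <- 1
  expect_identical(correlation_rank("a", "c", eq)$rank, 1L)
  expect_error(correlation_rank("a", "zz", eq), "absent")
})

test_that("scale-free fit accepts preferential-attachment degree structure", {
  g <- withr::with_seed(141, igraph::sample_pa(1500, m = 2, directed = FALSE))
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  storage.mode(adj) <- "double"
  diag(adj) <- 1
  res <- select_soft_threshold(adj, candidate_powers = 1)
  expect_false(res$fit_table$degenerate[1])
  expect_gte(res$fit_table$r_squared[1], 0.8)
})

test_that("soft-threshold selection flags degenerate input and is monotone in beta", {
  const <- matrix(0.5, 20, 20)
  diag(const) <- 1
  res <- select_soft_threshold(const, candidate_powers = c(1, 2, 4))
  expect_true(all(res$fit_table$degenerate))
  expect_true(is.na(res$beta))
  expect_false(res$criterion_met)
  # mean connectivity never increases with beta for |cor| <= 1
  withr::with_seed(142, {
    cm <- cor(matrix(rnorm(30 * 25), 25, 30))
  })
  res2 <- select_soft_threshold(cm, candidate_powers = 1:8)
  expect_true(all(diff(res2$fit_table$mean_connectivity) <= 1e-12))
})

test_that("TOM matches the triple-loop oracle and its closed forms", {
  # complete graph: all overlaps are 1
  n <- 5
  ones <- matrix(1, n, n)
  expect_true(all(abs(tom_similarity(ones) - 1) < 1e-12))

  # disconnected pair with no shared neighbours
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 0  # nodes 1-2 unlinked
  a[3, 4] <- a[4, 3] <- 1
  t4 <- tom_similarity(a)
  expect_identical(t4[1, 2], 0)

  # random adjacency vs the oracle
  withr::with_seed(151, {
    for (trial in 1:3) {
      r <- matrix(runif(36), 6, 6)
      adj <- (r + t(r)) / 2
      diag(adj) <- 0
      expect_lt(max(abs(tom_similarity(adj) - tom_oracle(adj))), 1e-12)
    }
  })

  expect_error(tom_similarity(matrix(c(0, 2, 2, 0), 2)), "\\[0, 1\\]")
  m <- matrix(runif(9), 3, 3)
  expect_error(tom_similarity(m), "symmetric")
})

test_that("module detection recovers planted blocks and honours its limits", {
  # two high-TOM blocks
  adj <- matrix(0.02, 12, 12)
  adj[1:6, 1:6] <- 0.9
  adj[7:12, 7:12] <- 0.9
  diag(adj) <- 0
  dimnames(adj) <- list(paste0("g", 1:12), paste0("g", 1:12))
  tom <- tom_similarity(adj)
  lab <- detect_modules(tom, cut_height = 0.5, min_module_size = 3)
  expect_true(same_partition(lab, rep(1:2, each = 6)))

  # cut height near 1: a single module
  lab1 <- detect_modules(tom, cut_height = 0.999, min_module_size = 3)
  expect_identical(max(lab1), 1L)
  expect_identical(length(unique(lab1)), 1L)

  # min size above n: everything is background
  lab0 <- detect_modules(tom, cut_height = 0.5, min_module_size = 13)
  expect_true(all(lab0 == 0L))
  expect_error(detect_modules(tom, cut_height = 1.5), "cut_height")
})

test_that("average linkage inside module detection matches the oracle", {
  withr::with_seed(161, {
    r <- matrix(runif(64), 8, 8)
    adj <- (r + t(r)) / 2
    diag(adj) <- 0
    tom <- tom_similarity(adj)
    hc <- hclust(as.dist(1 - tom), method = "average")
    for (k in 2:4) {
      expect_true(same_partition(cutree(hc, k = k),
                                 linkage_oracle(1 - tom, k, "average")))
    }
  })
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  bg <- sprintf("g%03d", 1:100)
  sets <- list(s1 = bg[1:5])
  res <- hypergeometric_enrichment(bg[1:5], sets, bg)
  expect_equal(res$p_hypergeom, 1 / choose(100, 5), tolerance = 1e-12)

  # zero overlap, or empty set/query: p = 1
  res0 <- hypergeometric_enrichment(bg[6:10], sets, bg)
  expect_identical(res0$p_hypergeom, 1)
  res_empty <- hypergeometric_enrichment(bg[1:5], list(s = character(0)), bg)
  expect_identical(res_empty$p_hypergeom, 1)

  # N = 20 instance vs full enumeration of all C(20, 6) draws
  bg20 <- letters[1:20]
  res20 <- hypergeometric_enrichment(bg20[1:6], list(s = bg20[1:8]), bg20)
  k <- res20$overlap_count
  expect_identical(k, 6L)
  # a 4-overlap query assembled explicitly
  q <- c(bg20[1:4], bg20[9:10])
  res4 <- hypergeometric_enrichment(q, list(s = bg20[1:8]), bg20)
  expect_equal(res4$p_hypergeom, hyper_enum_oracle(20, 8, 6, 4),
               tolerance = 1e-12)

  expect_error(hypergeometric_enrichment(c("zz"), sets, bg), "background")
})

test_that("tissue DE filtering and probe selection utilities work", {
  de <- data.frame(
    tissue = rep(c("brain", "liver"), each = 3),
    gene = c("a", "b", "c", "a", "d", "e"),
    p_adj = c(0.01, 0.2, 0.04, 0.5, 0.001, 0.04),
    log_fc = c(1.2, 2, 0.3, 0.7, -0.9, 0.58)
  )
  sets <- filter_tissue_de(de)
  expect_identical(sets$brain, "a")
  expect_identical(sort(sets$liver), c("d", "e"))

  probes <- data.frame(
    gene = c("g1", "g1", "g2"),
    probe = c("p1", "p2", "p3"),
    ds = c(0.2, 0.8, 0.5)
  )
  sel <- select_probe_by_stability(probes)
  expect_identical(sel$probe[sel$gene == "g1"], "p2")
  expect_identical(nrow(sel), 2L)
})
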