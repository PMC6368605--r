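# Shared fixtures and independent brute-force oracles for the test suite.
# Fixtures are generated in code; oracles are deliberately naive
# implementations kept separate from the package's computation paths.

small_atlas <- function(grid = c(12L, 12L, 12L), n_regions = 12L, seed = 99L) {
  make_atlas(grid, n_regions, seed = seed)
}

# paint a regional profile onto the atlas grid (zero-noise truth volume)
paint_profile <- function(profile, atlas) {
  vol <- array(NA_real_, dim = atlas$grid_shape)
  idx <- which(atlas$mask)
  vol[idx] <- profile[atlas$labels[idx]]
  vol
}

# --- oracles -----------------------------------------------------------

# Spearman via explicit midranks then Pearson
spearman_oracle <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# TOM by an explicit triple loop
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  out <- diag(n)
  k <- rowSums(a)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# agglomerative clustering by recomputing all inter-cluster distances at
# every merge (complete or average linkage)
linkage_oracle <- function(D, k, method = c("complete", "average")) {
  method <- match.arg(method)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- D[clusters[[i]], clusters[[j]], drop = FALSE]
        d <- if (method == "complete") max(dij) else mean(dij)
        if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  lab
}

# hypergeometric upper tail P(X >= k) by full enumeration of all draws
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the annotated set
  mean(hits >= k)
}

# brute-force barycentric interpolation: locate by testing every simplex
# (jittered coordinates), solve weights from the original coordinates
interp_oracle <- function(tess, values, queries) {
  vapply(seq_len(nrow(queries)), function(iq) {
    q <- queries[iq, ]
    for (t in seq_len(nrow(tess$simplices))) {
      s <- tess$simplices[t, ]
      Mj <- rbind(t(tess$jittered[s, , drop = FALSE]), 1)
      w <- tryCatch(solve(Mj, c(q, 1)), error = function(e) NULL)
      if (is.null(w) || any(w < -1e-9)) next
      Mo <- rbind(t(tess$points[s, , drop = FALSE]), 1)
      wo <- tryCatch(solve(Mo, c(q, 1)), error = function(e) w)
      return(sum(wo * values[s]))
    }
    NA_real_
  }, numeric(1))
}

# partition agreement up to relabelling
same_partition <- function(a, b) {
  isTRUE(all.equal(mclust::adjustedRandIndex(a, b), 1))
}
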