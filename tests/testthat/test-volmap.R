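test_that("border voxels match brute-force neighbour scans", {
  cube3 <- array(TRUE, c(3, 3, 3))
  b3 <- find_border_voxels(cube3)
  expect_identical(nrow(b3), 26L)  # all but the centre
  expect_false(any(b3[, 1] == 1 & b3[, 2] == 1 & b3[, 3] == 1))

  one <- array(TRUE, c(1, 1, 1))
  expect_identical(find_border_voxels(one), cbind(x = 0, y = 0, z = 0))

  cube5 <- array(TRUE, c(5, 5, 5))
  expect_identical(nrow(find_border_voxels(cube5)), 125L - 27L)

  expect_error(find_border_voxels(array(FALSE, c(3, 3, 3))), "empty mask")

  # brute force on an irregular mask
  a <- small_atlas()
  b <- find_border_voxels(a$mask)
  vox <- mask_coords(a$mask)
  is_border <- apply(vox, 1, function(v) {
    for (d in 1:3) for (s in c(-1, 1)) {
      nb <- v
      nb[d] <- nb[d] + s
      if (any(nb < 0) || any(nb > a$grid_shape - 1)) return(TRUE)
      if (!a$mask[matrix(nb + 1, 1)]) return(TRUE)
    }
    FALSE
  })
  expect_equal(b, vox[is_border, , drop = FALSE][
    order(vox[is_border, 1], vox[is_border, 2], vox[is_border, 3]), ],
    ignore_attr = TRUE)
})

make_bar_samples <- function(coords, values, gene = "g1") {
  structure(
    list(donor_id = "d", coords = coords,
         expression = matrix(values, ncol = 1, dimnames = list(NULL, gene)),
         gene_ids = gene),
    class = "voxgex_donor_samples"
  )
}

test_that("border labelling picks the nearest sample, ties to lowest index", {
  bar <- array(TRUE, c(9, 3, 3))
  border <- find_border_voxels(bar)

  # single sample: every border voxel takes its value
  s1 <- make_bar_samples(matrix(c(4, 1, 1), 1), 7.5)
  aug <- label_borders(s1, "g1", border)
  expect_true(all(aug$values[-1] == 7.5))
  expect_identical(nrow(aug$coords), 1L + nrow(border))

  # two samples at opposite ends: verify against exhaustive distances
  s2 <- make_bar_samples(rbind(c(0.2, 1, 1), c(8.1, 1.4, 0.9)), c(-1, 1))
  aug2 <- label_borders(s2, "g1", border)
  expected <- apply(border, 1, function(v) {
    d <- sqrt(colSums((t(s2$coords) - v)^2))
    s2$expression[which.min(d), 1]
  })
  expect_equal(unname(aug2$values[-(1:2), 1]), expected)

  # exact tie between samples 0 and 1 goes to the first
  s3 <- make_bar_samples(rbind(c(3, 1, 1), c(5, 1, 1)), c(10, 20))
  aug3 <- label_borders(s3, "g1", border)
  tie <- which(border[, 1] == 4)
  expect_true(all(aug3$values[2 + tie, 1] == 10))
})

test_that("barycentric interpolation reproduces affine fields exactly", {
  withr::with_seed(11, {
    for (trial in 1:5) {
      pts <- matrix(runif(150, 0, 10), 50, 3)
      cf <- runif(4, -3, 3)
      vals <- cf[1] + pts %*% cf[2:4]
      tess <- delaunay_tessellation(pts)
      q <- matrix(runif(90, 2, 8), 30, 3)
      v <- delaunay_interpolate(tess, as.numeric(vals), q, fallback = "na")
      inh <- attr(v, "in_hull")
      expect_gt(sum(inh), 0)
      expect_lt(max(abs(v[inh] - (cf[1] + q[inh, , drop = FALSE] %*% cf[2:4]))),
                1e-9)
    }
  })
})

test_that("interpolant matches the unit-tetrahedron closed form and the data", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tess <- delaunay_tessellation(pts)
  v <- delaunay_interpolate(tess, c(0, 0, 0, 1),
                            matrix(c(0.25, 0.25, 0.25), 1), fallback = "na")
  expect_equal(as.numeric(v), 0.25, tolerance = 1e-12)

  withr::with_seed(12, {
    pts <- matrix(runif(120), 40, 3)
    vals <- runif(40)
    tess <- delaunay_tessellation(pts)
    at_data <- delaunay_interpolate(tess, vals, pts)
    expect_equal(as.numeric(at_data), vals, tolerance = 1e-9)
  })
})

test_that("interpolation agrees with a brute-force simplex-location oracle", {
  withr::with_seed(13, {
    pts <- matrix(runif(150, 0, 5), 50, 3)
    vals <- rnorm(50)
    tess <- delaunay_tessellation(pts)
    q <- matrix(runif(60, 1, 4), 20, 3)
    mine <- delaunay_interpolate(tess, vals, q, fallback = "na")
    oracle <- interp_oracle(tess, vals, q)
    both <- !is.na(mine) & !is.na(oracle)
    expect_gt(sum(both), 10)
    expect_lt(max(abs(mine[both] - oracle[both])), 1e-9)
  })
})

test_that("tessellation-based interpolation matches an independent implementation", {
  # scipy's Qhull-based LinearNDInterpolator as an external oracle
  withr::with_seed(14, {
    pts <- matrix(runif(240, 0, 10), 80, 3)
    vals <- runif(80)
    q <- matrix(runif(300, 1, 9), 100, 3)
  })
  td <- withr::local_tempdir()
  write.table(cbind(pts, vals), file.path(td, "pts.txt"),
              row.names = FALSE, col.names = FALSE)
  write.table(q, file.path(td, "q.txt"), row.names = FALSE, col.names = FALSE)
  script <- file.path(td, "interp.py")
  writeLines(c(
    "import numpy as np, sys",
    "from scipy.interpolate import LinearNDInterpolator",
    "d = np.loadtxt(sys.argv[1]); q = np.loadtxt(sys.argv[2])",
    "f = LinearNDInterpolator(d[:, :3], d[:, 3])",
    "np.savetxt(sys.argv[3], f(q))"
  ), script)
  status <- system2("python",
                    c(script, file.path(td, "pts.txt"), file.path(td, "q.txt"),
                      file.path(td, "out.txt")))
  expect_identical(status, 0L)
  oracle <- scan(file.path(td, "out.txt"), quiet = TRUE)
  tess <- delaunay_tessellation(pts)
  mine <- delaunay_interpolate(tess, vals, q, fallback = "na")
  expect_identical(is.na(as.numeric(mine)), is.na(oracle))
  both <- !is.na(oracle)
  expect_lt(max(abs(mine[both] - oracle[both])), 1e-8)
})

test_that("degenerate point sets are rejected with advice to jitter", {
  flat <- cbind(matrix(runif(40), 20, 2), 1)
  expect_error(delaunay_tessellation(flat), "jitter")
  expect_error(delaunay_tessellation(matrix(runif(9), 3, 3)), "at least 4")
})

test_that("volumes preserve the sample value range and fill every mask voxel", {
  atlas <- small_atlas()
  lib <- simulate_gene_library(atlas, 5, 1, 3, seed = 21)
  d <- sample_donor(atlas, lib$regional_profiles, 100,
                    measurement_noise_sd = 0.5, seed = 22)
  vs <- build_expression_volumes(d, atlas)
  expect_true(all(is.finite(vs$values)))
  for (g in vs$gene_ids) {
    rng <- range(d$expression[, g])
    expect_gte(min(vs$values[, g]), rng[1])
    expect_lte(max(vs$values[, g]), rng[2])
  }
})

test_that("volume construction is deterministic (bit-identical reruns)", {
  atlas <- small_atlas()
  lib <- simulate_gene_library(atlas, 3, 1, 3, seed = 31)
  d <- sample_donor(atlas, lib$regional_profiles, 80, seed = 32)
  v1 <- build_expression_volumes(d, atlas)
  v2 <- build_expression_volumes(d, atlas)
  expect_identical(v1$values, v2$values)
})

test_that("averaging volumes is the voxelwise mean with donor_id 'average'", {
  atlas <- small_atlas()
  lib <- simulate_gene_library(atlas, 3, 1, 3, seed = 41)
  d <- sample_donor(atlas, lib$regional_profiles, 60, seed = 42)
  vs <- build_expression_volumes(d, atlas)

  one <- average_volumes(list(vs))
  expect_equal(one$values, vs$values)
  expect_identical(one$donor_id, "average")

  neg <- vs
  neg$values <- -vs$values
  zero <- average_volumes(list(vs, neg))
  expect_true(all(abs(zero$values) < 1e-12))

  bad <- build_expression_volumes(d, small_atlas(grid = c(10L, 12L, 12L)))
  expect_error(average_volumes(list(vs, bad)), "mismatch")
})

test_that("zero-noise dense sampling recovers the regional truth exactly", {
  atlas <- small_atlas(n_regions = 6L)
  lib <- simulate_gene_library(atlas, 4, 1, 3, seed = 51)
  donors <- lapply(1:3, function(i)
    sample_donor(atlas, lib$regional_profiles, sum(atlas$mask),
                 measurement_noise_sd = 0, seed = 50 + i,
                 donor_id = paste0("d", i), coord_jitter = 0))
  vols <- lapply(donors, build_expression_volumes, atlas = atlas)
  avg <- average_volumes(vols)
  truth <- t(lib$regional_profiles[, atlas$labels[avg$mask_idx]])
  # interpolation tolerance: voxels on region boundaries mix the point
  # values of coincident sample/border pseudo-points at the 1e-6 jitter
  # scale; region interiors are exact
  expect_equal(unname(avg$values), unname(truth), tolerance = 1e-4)
})
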