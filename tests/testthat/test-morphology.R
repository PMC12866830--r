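test_that("the registry holds exactly 67 uniquely named descriptors", {
  reg <- descriptor_registry()
  expect_length(reg, 67)
  expect_equal(anyDuplicated(reg), 0)
  fam <- attr(reg, "family")
  expect_equal(as.vector(table(fam)[c("point", "geometric", "moment",
                                      "boundary", "skeleton", "fractal",
                                      "composite")]),
               c(8, 16, 12, 12, 10, 4, 5))
})

test_that("a dense disc yields a full, finite, near-circular profile", {
  pts <- disc_points(500, r = 0.1, center = c(2, 2), seed = 41)
  agg <- as_aggregate(pts$x, pts$y)
  d <- compute_descriptors(agg)
  expect_length(d, 67)
  expect_equal(names(d), as.vector(descriptor_registry()))
  expect_true(all(is.finite(d)))
  expect_gte(d[["circularity"]], 0.9)
  expect_lte(d[["circularity"]], 1 + 1e-9)
  expect_gt(d[["area"]], 0)
  expect_gt(d[["perimeter"]], 0)
  expect_gt(d[["major_axis"]], 0)
  expect_equal(d[["n_locs"]], 500)
  # a disc is nearly isotropic
  expect_lt(d[["eccentricity"]], 0.5)
  expect_lt(d[["elongation"]], 0.2)
})

test_that("descriptors are invariant to translation", {
  pts <- disc_points(300, r = 0.08, center = c(1, 1), seed = 7)
  d0 <- compute_descriptors(as_aggregate(pts$x, pts$y))
  d1 <- compute_descriptors(as_aggregate(pts$x + 10, pts$y - 3))
  # curvature zero-crossings count sign changes of a quantity that hovers
  # near zero on a smooth boundary; allow one flip from rounding
  expect_lte(abs(d0[["curv_zero_crossings"]] - d1[["curv_zero_crossings"]]), 2)
  keep <- setdiff(names(d0), "curv_zero_crossings")
  expect_equal(d0[keep], d1[keep], tolerance = 1e-6)
})

test_that("descriptors scale with their dimensional exponents under dilation", {
  withr::with_seed(23, {
    base <- disc_points(260, r = 0.1)
    base$x <- base$x * 1.7  # anisotropic so orientation-bearing terms are stable
  })
  s <- 2
  d1 <- compute_descriptors(as_aggregate(base$x, base$y, alpha_radius = 0.06))
  d2 <- compute_descriptors(as_aggregate(base$x * s, base$y * s,
                                         alpha_radius = 0.06 * s))
  lengths <- c("perimeter", "equiv_diameter", "major_axis", "minor_axis",
               "nn_dist_mean", "radius_gyration", "radial_mean",
               "skel_length", "bbox_width", "bbox_height")
  for (f in lengths) expect_equal(d2[[f]], s * d1[[f]], tolerance = 1e-6,
                                  label = f)
  expect_equal(d2[["area"]], s^2 * d1[["area"]], tolerance = 1e-6)
  expect_equal(d2[["loc_density"]], d1[["loc_density"]] / s^2,
               tolerance = 1e-6)
  dimensionless <- c("circularity", "solidity", "convexity", "aspect_ratio",
                     "eccentricity", "elongation", "compactness",
                     "norm_radius_gyration", "hu1", "hu2",
                     "moment_anisotropy", "radial_cv", "skel_tortuosity")
  for (f in dimensionless) expect_equal(d2[[f]], d1[[f]], tolerance = 1e-6,
                                        label = f)
})

test_that("degenerate geometry raises a descriptor error naming the family", {
  x <- seq(0, 1, length.out = 20)
  agg <- try(as_aggregate(x, 2 * x, alpha_radius = 0.05), silent = TRUE)
  if (inherits(agg, "aggregate")) {
    expect_error(compute_descriptors(agg), "family")
  } else {
    succeed("collinear input already rejected at boundary construction")
  }
  pts <- disc_points(9, r = 0.05, seed = 1)
  expect_error(compute_descriptors(as_aggregate(pts$x, pts$y)), ">= 10")
})

test_that("PCA on collinear feature data concentrates variance on PC1", {
  withr::with_seed(15, {
    t <- rnorm(40)
    mat <- outer(t, runif(12, -2, 2)) +
      matrix(rep(runif(12), each = 40), nrow = 40)
  })
  colnames(mat) <- paste0("f", 1:12)
  emb <- run_pca(mat)
  expect_gte(emb$explained[1], 1 - 1e-9)
})

test_that("PCA scores reconstruct the scaled data and ignore duplication", {
  withr::with_seed(16, mat <- matrix(rnorm(35 * 8), nrow = 35))
  colnames(mat) <- paste0("f", 1:8)
  emb <- run_pca(mat)
  scaled <- scale(mat, center = emb$scaling$center, scale = emb$scaling$scale)
  recon <- emb$scores %*% t(emb$loadings)
  expect_lt(max(abs(recon - scaled)), 1e-8)
  # duplicating every observation leaves the loadings unchanged
  emb2 <- run_pca(rbind(mat, mat))
  expect_equal(emb2$loadings, emb$loadings, tolerance = 1e-8)
  # explained-variance fractions are sorted and sum to 1
  expect_true(all(diff(emb$explained) <= 1e-12))
  expect_equal(sum(emb$explained), 1)

  expect_error(run_pca(mat[1, , drop = FALSE]), "at least 2")
  const <- cbind(mat, constant = 1)
  expect_message(emb3 <- run_pca(const), "zero-variance")
  expect_equal(emb3$dropped, "constant")
})

test_that("polygon Jaccard matches closed-form cases", {
  sq <- square_poly(0, 0, 1)
  expect_equal(polygon_jaccard(sq, sq), 1)
  far <- square_poly(5, 5, 1)
  expect_equal(polygon_jaccard(sq, far), 0)
  # two unit squares offset by half a side: intersection 1/2, union 3/2
  half <- square_poly(0.5, 0, 1)
  expect_equal(polygon_jaccard(sq, half), 1 / 3, tolerance = 1e-6)
  # literal intersection-over-summed-areas variant
  expect_equal(polygon_jaccard(sq, half, method = "sum"), 1 / 4,
               tolerance = 1e-6)
  expect_equal(polygon_jaccard(sq, half), polygon_jaccard(half, sq))
})

test_that("group footprints overlap fully for identical groups, not at all for distant ones", {
  withr::with_seed(27, {
    pts <- matrix(rnorm(60 * 2), ncol = 2)
  })
  scores <- rbind(pts, pts)
  emb <- structure(list(scores = cbind(scores, 0), groups = rep(c("a", "b"),
                                                                each = 60)),
                   class = "group_embedding")
  same <- group_overlap_jaccard(emb, pair = c("a", "b"), plane = c(1, 2))
  expect_equal(same$jaccard, 1)
  far <- rbind(pts, pts + 50)
  emb2 <- structure(list(scores = cbind(far, 0), groups = rep(c("a", "b"),
                                                              each = 60)),
                    class = "group_embedding")
  expect_equal(group_overlap_jaccard(emb2, pair = c("a", "b"))$jaccard, 0)
  # overlap decreases monotonically as one group shifts away
  jac <- vapply(c(0, 1.5, 3, 6), function(d) {
    e <- structure(list(scores = cbind(rbind(pts, pts + d), 0),
                        groups = rep(c("a", "b"), each = 60)),
                   class = "group_embedding")
    group_overlap_jaccard(e, pair = c("a", "b"), boundary = "hull")$jaccard
  }, numeric(1))
  expect_true(all(diff(jac) <= 1e-9))
  expect_error(group_overlap_jaccard(
    structure(list(scores = cbind(pts[1:4, ], 0),
                   groups = c("a", "a", "b", "b")),
              class = "group_embedding"), pair = c("a", "b")),
    "fewer than 3")
})

test_that("distinct morphological populations separate in the embedding", {
  nano <- lapply(1:12, function(i) {
    pts <- disc_points(150, r = 0.05, seed = 100 + i)
    as_aggregate(pts$x, pts$y)
  })
  micro <- lapply(1:12, function(i) {
    spec <- planted_aggregate(c(0, 0), "fibril", "micro", 1.6,
                              600, angle = i)
    pts <- sample_aggregate(spec, jitter_sigma = 0.01, rng_seed = 200 + i)
    as_aggregate(pts$x, pts$y)
  })
  mat <- compute_descriptor_matrix(c(nano, micro))
  groups <- rep(c("nano", "micro"), each = 12)
  emb <- suppressMessages(run_pca(mat, groups))
  sil <- cluster::silhouette(as.integer(factor(groups)),
                             dist(emb$scores[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
  # and their footprints separate too
  ov <- group_overlap_jaccard(emb, pair = c("nano", "micro"),
                              boundary = "hull")
  expect_lt(ov$jaccard, 0.5)
})

test_that("descriptor summaries mirror figure-style panels", {
  pts <- disc_points(200, r = 0.0564, seed = 3)  # area ~ 0.01 um^2
  agg <- as_aggregate(pts$x, pts$y)
  mat <- compute_descriptor_matrix(list(agg))
  s <- descriptor_summaries(mat, groups = "ctrl",
                            features = c("area", "circularity"))
  expect_equal(nrow(s$group_summary), 2)
  a_row <- s$values[s$values$feature == "area", ]
  expect_equal(a_row$value, log10(mat[1, "area"]))
  expect_lt(abs(a_row$value - (-2)), 0.15)
  raw <- descriptor_summaries(mat, groups = "ctrl", features = "n_locs")
  expect_equal(raw$values$value, 200)
  expect_error(descriptor_summaries(mat, "ctrl", features = "volume"),
               "unknown descriptor")
})
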