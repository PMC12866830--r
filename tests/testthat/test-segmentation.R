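test_that("a regular grid tessellates into exact interior cells", {
  g <- expand.grid(x = seq(0.05, 0.95, by = 0.1),
                   y = seq(0.05, 0.95, by = 0.1))
  fov <- new_fov(data.frame(x = g$x, y = g$y, frame = 0L), c(1, 1))
  tess <- compute_voronoi(fov)
  expect_equal(tess$n, 100)
  expect_true(all(abs(tess$area[tess$bounded] - 0.01) < 1e-9))
  # bounded interior cells cannot exceed the FOV area in total
  expect_lte(sum(tess$area[tess$bounded]), 1 + 1e-9)
})

test_that("degenerate point sets are rejected", {
  expect_error(compute_voronoi(new_fov(data.frame(x = c(1, 2), y = c(1, 2),
                                                  frame = 0L), c(5, 5))),
               "degenerate")
  expect_error(compute_voronoi(new_fov(data.frame(x = 1:5, y = 1:5,
                                                  frame = 0L), c(6, 6))),
               "collinear")
})

test_that("cell areas agree with a nearest-site grid oracle", {
  withr::with_seed(3, {
    x <- runif(30, 0, 1); y <- runif(30, 0, 1)
  })
  fov <- new_fov(data.frame(x = x, y = y, frame = 0L), c(1, 1))
  tess <- compute_voronoi(fov)
  oracle <- grid_voronoi_areas(x, y, c(1, 1), n_grid = 500)
  # compare cells safely interior to the window (grid oracle clips at it)
  interior <- tess$bounded & x > 0.2 & x < 0.8 & y > 0.2 & y < 0.8 &
    tess$area < 0.02
  expect_gte(sum(interior), 3)
  expect_true(all(abs(tess$area[interior] - oracle[interior]) < 0.002))
})

test_that("tessellation adjacency matches a brute-force Delaunay oracle", {
  withr::with_seed(8, {
    x <- runif(30, 0, 5); y <- runif(30, 0, 5)
  })
  fov <- new_fov(data.frame(x = x, y = y, frame = 0L), c(5, 5))
  tess <- compute_voronoi(fov)
  got <- unique(t(apply(tess$edges, 1, sort)))
  want <- brute_delaunay_edges(x, y)
  key <- function(m) sort(paste(m[, 1], m[, 2]))
  expect_equal(key(got), key(want))
})

test_that("two dense blobs in sparse background give exactly two clusters", {
  withr::with_seed(21, {
    blob1 <- disc_points(120, r = 0.08, center = c(1, 1))
    blob2 <- disc_points(120, r = 0.08, center = c(4, 4))
    bg <- data.frame(x = runif(40, 0, 5), y = runif(40, 0, 5))
  })
  locs <- rbind(blob1, blob2, bg)
  fov <- new_fov(data.frame(x = locs$x, y = locs$y, frame = 0L), c(5, 5))
  tess <- compute_voronoi(fov)
  params <- segmentation_params(voronoi_area_threshold = 0.002)
  clusters <- threshold_and_cluster(fov, tess, params)
  clusters <- filter_min_locs(clusters, 10)
  expect_length(clusters, 2)
  planted <- c(rep(1, 120), rep(2, 120), rep(0, 40))
  for (cl in clusters) {
    expect_equal(length(unique(planted[cl$members])), 1)
    expect_gte(cl$n_locs, 90)
  }
  # memberships equal the exhaustive adjacency-component oracle
  retained <- which(tess$bounded & tess$area <= 0.002)
  oracle <- bfs_components(retained, tess$edges)
  oracle <- Filter(function(m) length(m) >= 10, oracle)
  got <- lapply(clusters, `[[`, "members")
  expect_equal(canonical_partition(got), canonical_partition(oracle))
})

test_that("threshold extremes behave as documented", {
  withr::with_seed(5, {
    pts <- disc_points(300, r = 2, center = c(5, 5))
  })
  fov <- new_fov(data.frame(x = pts$x, y = pts$y, frame = 0L), c(10, 10))
  tess <- compute_voronoi(fov)
  none <- threshold_and_cluster(fov, tess,
                                segmentation_params(voronoi_area_threshold =
                                                      min(tess$area[tess$bounded]) / 2))
  expect_length(none, 0)
  all_in <- threshold_and_cluster(fov, tess,
                                  segmentation_params(voronoi_area_threshold = 1e6))
  expect_length(all_in, 1)
  expect_equal(sort(all_in[[1]]$members), which(tess$bounded))
})

test_that("the minimum-localization filter is inclusive at the boundary", {
  cls <- list(fake_cluster(0.01, n_locs = 9, id = 1),
              fake_cluster(0.01, n_locs = 10, id = 2),
              fake_cluster(0.01, n_locs = 25, id = 3))
  kept <- filter_min_locs(cls, 10)
  expect_equal(vapply(kept, `[[`, numeric(1), "id"), c(2, 3))
  expect_length(filter_min_locs(list(), 10), 0)
})

test_that("clusters partition retained localizations and are threshold-monotone", {
  sim <- generate_fov(rng_seed = 17, extent = c(25, 25),
                      n_per_class = c(nano = 5, intermediate = 2, micro = 0))
  tess <- compute_voronoi(sim$fov)
  thr_lo <- 1.5e-4; thr_hi <- 3e-4
  lo <- threshold_and_cluster(sim$fov, tess,
                              segmentation_params(voronoi_area_threshold = thr_lo))
  hi <- threshold_and_cluster(sim$fov, tess,
                              segmentation_params(voronoi_area_threshold = thr_hi))
  mem_lo <- unlist(lapply(lo, `[[`, "members"))
  mem_hi <- unlist(lapply(hi, `[[`, "members"))
  expect_equal(anyDuplicated(mem_lo), 0)
  expect_equal(anyDuplicated(mem_hi), 0)
  expect_true(all(mem_lo %in% mem_hi))

  again <- threshold_and_cluster(sim$fov, tess,
                                 segmentation_params(voronoi_area_threshold = thr_hi))
  expect_identical(canonical_partition(lapply(hi, `[[`, "members")),
                   canonical_partition(lapply(again, `[[`, "members")))
})

test_that("pure-noise fields yield no clusters after the min-locs filter", {
  sim <- generate_fov(n_per_class = c(nano = 0, intermediate = 0, micro = 0),
                      noise = noise_model(uniform_rate = 3,
                                          cluster_rate = 0.1),
                      extent = c(20, 20), rng_seed = 19)
  clusters <- segment_fov(sim$fov, segmentation_params())
  expect_length(clusters, 0)
})

test_that("alpha shapes recover disc geometry and fall back to hulls", {
  pts <- disc_points(500, r = 0.1, center = c(0.5, 0.5), seed = 2)
  shp <- alpha_shape(pts$x, pts$y, alpha = 0.05)
  expect_false(shp$used_hull)
  expect_lt(abs(shp$area - pi * 0.01), 0.2 * pi * 0.01)
  circ <- 4 * pi * shp$area / shp$perimeter^2
  expect_gte(circ, 0.9)
  expect_lte(circ, 1 + 1e-9)
  # tiny alpha: no triangle survives, hull fallback
  tiny <- alpha_shape(pts$x, pts$y, alpha = 1e-6)
  expect_true(tiny$used_hull)
  expect_gt(tiny$area, 0)
})
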