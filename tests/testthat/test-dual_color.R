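test_that("enrichment scores follow the difference-over-total formula", {
  expect_equal(enrichment_score(40, 0), 1)
  expect_equal(enrichment_score(0, 40), -1)
  expect_equal(enrichment_score(7, 7), 0)
  expect_equal(enrichment_score(10, 1), 9 / 11)
  expect_error(enrichment_score(0, 0), "undefined")
})

test_that("enrichment is antisymmetric, bounded and count-scale invariant", {
  grid <- expand.grid(a = c(1, 3, 10, 57, 400), b = c(0, 2, 10, 57, 391))
  s <- enrichment_score(grid$a, grid$b)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(s, -enrichment_score(grid$b, grid$a))
  expect_equal(s, enrichment_score(7 * grid$a, 7 * grid$b))
})

test_that("modification categories respect the 0.8 cutoffs", {
  expect_equal(classify_modification(0.9), "SINGLY_A")
  expect_equal(classify_modification(0.0), "DUALLY")
  expect_equal(classify_modification(-0.85), "SINGLY_B")
  # the boundary itself is dually modified (between -0.8 and 0.8, inclusive)
  expect_equal(classify_modification(c(0.8, -0.8)), c("DUALLY", "DUALLY"))
  expect_error(classify_modification(1.2), "outside")
  # category is consistent with score and cutoff over a sweep
  s <- seq(-1, 1, by = 0.05)
  cat <- classify_modification(s, cutoff = 0.8)
  expect_equal(cat == "SINGLY_A", s > 0.8)
  expect_equal(cat == "SINGLY_B", s < -0.8)
})

test_that("merging with an empty channel reduces to single-color segmentation", {
  sim <- generate_fov(rng_seed = 33, extent = c(25, 25),
                      n_per_class = c(nano = 5, intermediate = 2, micro = 0))
  empty <- new_fov(data.frame(x = numeric(0), y = numeric(0),
                              frame = integer(0)), c(25, 25))
  merged <- merge_and_segment(sim$fov, empty)
  single <- segment_fov(sim$fov)
  expect_equal(length(merged), length(single))
  expect_equal(canonical_partition(lapply(merged, `[[`, "members")),
               canonical_partition(lapply(single, `[[`, "members")))
  # per-channel counts sum to the member count in every cluster
  for (cl in merged)
    expect_equal(sum(cl$n_per_channel), cl$n_locs)
  expect_error(merge_fovs(sim$fov, new_fov(data.frame(x = 1, y = 1,
                                                      frame = 0L), c(9, 9))),
               "extent")
})

test_that("overlap scores capture co-sampled, disjoint and nested channels", {
  # both channels drawn from the same disc: near-total overlap
  pts <- disc_points(500, r = 0.1, center = c(1, 1), seed = 9)
  ch <- rep(c("A", "B"), length.out = 500)
  co <- as_aggregate(pts$x, pts$y, channel = ch)
  ov <- overlap_score(co)
  expect_true(ov$defined)
  expect_gte(ov$score, 85)
  expect_equal(ov$score, min(ov$overlap_A, ov$overlap_B))

  # disjoint discs: zero overlap
  a <- disc_points(200, r = 0.08, center = c(1, 1), seed = 10)
  b <- disc_points(200, r = 0.08, center = c(3, 3), seed = 11)
  dis <- as_aggregate(c(a$x, b$x), c(a$y, b$y),
                      channel = rep(c("A", "B"), each = 200))
  expect_equal(overlap_score(dis)$score, 0)

  # A strictly inside B: A's directional overlap ~ 100, B's is the reported
  small <- disc_points(250, r = 0.05, center = c(2, 2), seed = 12)
  big <- disc_points(900, r = 0.15, center = c(2, 2), seed = 13)
  nest <- as_aggregate(c(small$x, big$x), c(small$y, big$y),
                       channel = rep(c("A", "B"), times = c(250, 900)))
  ovn <- overlap_score(nest)
  expect_gte(ovn$overlap_A, 95)
  expect_lt(ovn$overlap_B, 50)
  expect_equal(ovn$score, ovn$overlap_B)
  # area-ratio oracle: (r_small / r_big)^2 ~ 11%
  expect_lt(abs(ovn$overlap_B - 100 * (0.05 / 0.15)^2), 8)

  # a channel with < 3 localizations gets score 0, flagged
  few <- as_aggregate(c(a$x, 2, 2.01), c(a$y, 2, 2.01),
                      channel = c(rep("A", 200), "B", "B"))
  ovf <- overlap_score(few)
  expect_false(ovf$defined)
  expect_equal(ovf$score, 0)
})

test_that("low-overlap merged pairs are split into channel-pure clusters", {
  bp <- generate_blob_pair_fov(n_pairs = 4, rng_seed = 5)
  seg <- merge_and_segment(bp$fov, NULL)
  expect_equal(length(seg), 4)
  scores <- vapply(seg, function(cl) overlap_score(cl)$score, numeric(1))
  expect_true(all(scores < 30))
  out <- resegment_low_overlap(seg, bp$fov)
  expect_equal(length(out), 8)
  purity <- vapply(out, function(cl) length(unique(cl$channel)), numeric(1))
  expect_true(all(purity == 1))
  # localization count is preserved and memberships still partition
  expect_equal(sum(vapply(out, `[[`, numeric(1), "n_locs")),
               sum(vapply(seg, `[[`, numeric(1), "n_locs")))
  mem <- unlist(lapply(out, `[[`, "members"))
  expect_equal(anyDuplicated(mem), 0)
  expect_setequal(mem, unlist(lapply(seg, `[[`, "members")))
  # each split cluster matches one planted disc
  for (cl in out) {
    labs <- bp$truth$labels[cl$members]
    expect_gte(max(table(labs)) / length(labs), 0.99)
  }
})

test_that("high-overlap and micro-sized clusters pass through untouched", {
  pts <- disc_points(400, r = 0.1, center = c(1, 1), seed = 14)
  hi <- as_aggregate(pts$x, pts$y,
                     channel = rep(c("A", "B"), length.out = 400))
  fov <- new_fov(data.frame(x = pts$x, y = pts$y, frame = 0L,
                            channel = hi$channel), c(5, 5))
  out <- resegment_low_overlap(list(hi), fov)
  expect_length(out, 1)
  expect_equal(sort(out[[1]]$members), sort(hi$members))

  # micro-sized, channel-disjoint cluster: area gate applies first
  a <- disc_points(2500, r = 0.35, center = c(1.0, 1.0), seed = 15)
  b <- disc_points(2500, r = 0.35, center = c(1.9, 1.0), seed = 16)
  micro <- as_aggregate(c(a$x, b$x), c(a$y, b$y),
                        channel = rep(c("A", "B"), each = 2500))
  expect_gt(micro$area, 0.15)
  expect_lt(overlap_score(micro)$score, 30)
  fov2 <- new_fov(data.frame(x = micro$x, y = micro$y, frame = 0L,
                             channel = micro$channel), c(5, 5))
  out2 <- resegment_low_overlap(list(micro), fov2)
  expect_length(out2, 1)
  expect_equal(out2[[1]]$n_locs, 5000)
})

test_that("planted enrichment is recovered on a dual-color field of view", {
  sim <- generate_fov(rng_seed = 55, extent = c(30, 30),
                      n_per_class = c(nano = 6, intermediate = 3, micro = 1),
                      mix = enrichment_mix())
  res <- analyze_dual_fov(sim$fov)
  rm <- recovery_metrics(res$clusters, sim$truth)
  cm <- rm$cluster_match[rm$cluster_match$n_locs >= 50, ]
  err <- abs(cm$recovered_score - cm$planted_enrichment)
  expect_gte(nrow(cm), 5)
  expect_lt(mean(err, na.rm = TRUE), 0.05)
})
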