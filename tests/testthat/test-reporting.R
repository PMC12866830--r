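make_fov_result <- function(group, replicate, fov_id, counts,
                            extent = c(50, 50)) {
  clusters <- unlist(lapply(names(counts), function(k)
    replicate(counts[[k]], fake_cluster(0.01, size_class = k),
              simplify = FALSE)), recursive = FALSE)
  list(group = group, replicate = replicate, fov_id = fov_id,
       fov = new_fov(data.frame(x = numeric(0), y = numeric(0),
                                frame = integer(0)), extent),
       clusters = clusters)
}

test_that("density per unit area is count over extent area", {
  fov <- new_fov(data.frame(x = numeric(0), y = numeric(0),
                            frame = integer(0)), c(50, 50))
  expect_equal(density_per_unit_area(5, fov), 0.002)
  expect_equal(density_per_unit_area(list(), fov), 0)
  big <- new_fov(data.frame(x = numeric(0), y = numeric(0),
                            frame = integer(0)), c(100, 50))
  expect_equal(density_per_unit_area(5, big), 0.001)
})

test_that("class percentages normalize case means to 100", {
  res <- list(
    make_fov_result("ctrl", "r1", "f1", c(nano = 90, intermediate = 8,
                                          micro = 2)),
    make_fov_result("ctrl", "r1", "f2", c(nano = 90, intermediate = 8,
                                          micro = 2)))
  tab <- cohort_table(res)
  expect_equal(tab$density, tab$count / 2500)
  pc <- class_percentages(tab, level = "group")
  expect_equal(pc$nano, 90)
  expect_equal(pc$intermediate, 8)
  expect_equal(pc$micro, 2)
  expect_lt(abs(sum(pc[1, c("nano", "intermediate", "micro")]) - 100), 1e-9)

  solo <- cohort_table(list(make_fov_result("x", "r1", "f1",
                                            c(nano = 7, intermediate = 0,
                                              micro = 0))))
  ps <- class_percentages(solo, level = "group")
  expect_equal(unlist(ps[1, c("nano", "intermediate", "micro")],
                      use.names = FALSE), c(100, 0, 0))

  withzero <- rbind(tab, cohort_table(list(
    make_fov_result("empty", "r1", "f1", c(nano = 0, intermediate = 0,
                                           micro = 0)))))
  expect_message(pz <- class_percentages(withzero, level = "group"),
                 "omitting")
  expect_false("empty" %in% pz$group)
})

test_that("modification percentages sum to 100 and recover planted mixes", {
  rec <- data.frame(id = as.character(1:10), n_A = 1, n_B = 1, score = 0,
                    category = "DUALLY", size_class = "nano")
  mp <- modification_percentages(rec)
  expect_equal(mp$dually, 100)

  withr::with_seed(61, {
    cat <- sample(c(rep("DUALLY", 60), rep("SINGLY_A", 25),
                    rep("SINGLY_B", 15)))
  })
  rec2 <- data.frame(id = as.character(seq_along(cat)), n_A = 1, n_B = 1,
                     score = 0, category = cat, size_class = "nano")
  mp2 <- modification_percentages(rec2)
  expect_equal(mp2$dually, 60)
  expect_equal(mp2$singly_A + mp2$singly_B + mp2$dually, 100)
})

test_that("rank-sum on replicate means matches exhaustive enumeration", {
  cases <- list(list(x = c(1.2, 3.4, 2.2, 5.1), y = c(4.4, 6.2, 7.1, 5.5)),
                list(x = c(10, 12, 9), y = c(11, 13, 15, 14, 8)),
                list(x = c(0.1, 0.9, 0.5, 0.7), y = c(0.2, 0.4, 0.3, 0.6)))
  for (cs in cases) {
    got <- ranksum_compare(cs$x, cs$y)
    expect_equal(got$p_value, enum_ranksum_p(cs$x, cs$y), tolerance = 1e-12)
    # two-sided p is symmetric in the group order
    expect_equal(got$p_value, ranksum_compare(cs$y, cs$x)$p_value)
  }
  same <- ranksum_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(ranksum_compare(1, c(1, 2)), "at least 2")
  # one-sided variant detects a decrease
  lo <- c(1, 2, 1.5, 1.2); hi <- c(5, 6, 7, 5.5)
  expect_lt(ranksum_compare(lo, hi, alternative = "less")$p_value, 0.05)
})

test_that("channel count correlations behave on proportional and independent counts", {
  prop <- lapply(1:20, function(i) fake_cluster(0.01, id = i, n_A = i,
                                                n_B = 2 * i))
  cc <- channel_correlation(prop)
  expect_equal(cc$pearson, 1)
  anti <- lapply(1:20, function(i) fake_cluster(0.01, id = i, n_A = i,
                                                n_B = 40 - i))
  expect_equal(channel_correlation(anti)$pearson, -1)
  withr::with_seed(77, {
    ind <- lapply(1:200, function(i)
      fake_cluster(0.01, id = i, n_A = rpois(1, 50), n_B = rpois(1, 50)))
  })
  expect_lt(abs(channel_correlation(ind)$pearson), 0.2)
  flat <- lapply(1:5, function(i) fake_cluster(0.01, id = i, n_A = 10,
                                               n_B = i))
  expect_false(channel_correlation(flat)$defined)
  expect_error(channel_correlation(prop[1:2]), "at least 3")
})

test_that("single- versus dual-color count comparisons detect planted deficits", {
  withr::with_seed(88, {
    single <- lapply(1:60, function(i)
      fake_cluster(0.01, n_locs = rpois(1, 100), id = i,
                   size_class = "nano"))
    matched <- lapply(1:60, function(i)
      fake_cluster(0.01, n_locs = rpois(1, 100), id = i,
                   size_class = "nano"))
    halved <- lapply(1:60, function(i)
      fake_cluster(0.01, n_locs = rpois(1, 50), id = i, size_class = "nano"))
  })
  ok <- single_vs_dual_counts(single, matched)
  expect_gt(ok$p_value, 0.05)
  bad <- single_vs_dual_counts(single, halved)
  expect_lt(bad$p_value, 0.05)
})
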