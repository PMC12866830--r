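#!/usr/bin/env Rscript
# Morphological profiling of nano-aggregates and PCA group overlap.
#
# Computes the 67-descriptor profile for every nano-aggregate recovered in
# 02_segment_classify.R, embeds the cohort by unit-variance PCA, quantifies
# pairwise group overlap with the Jaccard index of footprint polygons in the
# PC1-PC2 plane, and summarizes the figure-style panels (log10 circularity,
# major axis, area).

suppressPackageStartupMessages(library(aggrepaint))

fov_results <- readRDS("scratch/fov_results.rds")
fov_results <- Filter(function(r) r$group != "dephos", fov_results)

recs <- do.call(rbind, lapply(fov_results, function(r) {
  nano <- Filter(function(cl) identical(cl$size_class, "nano"), r$clusters)
  if (length(nano) == 0) return(NULL)
  data.frame(group = r$group, replicate = r$replicate,
             idx = seq_along(nano))
}))
clusters <- unlist(lapply(fov_results, function(r)
  Filter(function(cl) identical(cl$size_class, "nano"), r$clusters)),
  recursive = FALSE)
stopifnot(nrow(recs) == length(clusters))

mat <- compute_descriptor_matrix(clusters)
emb <- run_pca(mat, groups = recs$group)
write.csv(cbind(recs, emb$scores[, 1:3]),
          "results/tables/nano_pca_scores.csv", row.names = FALSE)
write.csv(data.frame(component = seq_along(emb$explained),
                     explained = emb$explained),
          "results/tables/nano_pca_explained.csv", row.names = FALSE)

ov <- pairwise_group_overlap(emb)
write.csv(ov, "results/tables/nano_group_jaccard.csv", row.names = FALSE)

summ <- descriptor_summaries(mat, recs$group,
                             features = c("circularity", "major_axis",
                                          "area"),
                             replicates = recs$replicate)
write.csv(summ$replicate_means, "results/tables/nano_morphology_replicate_means.csv",
          row.names = FALSE)

cat(sprintf("profiled %d nano-aggregates; PC1-2 explain %.1f%% of variance\n",
            nrow(mat), 100 * sum(emb$explained[1:2])))
cat("pairwise PCA-footprint Jaccard overlap:\n")
print(ov, digits = 2)
cat("\ngroup means of log10 panels:\n")
print(stats::aggregate(value ~ feature + group, data = summ$values,
                       FUN = mean), digits = 3)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(PC1 = emb$scores[, 1], PC2 = emb$scores[, 2],
                   group = recs$group)
  p <- ggplot2::ggplot(df, ggplot2::aes(PC1, PC2, colour = group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(title = "Nano-aggregate morphology (PCA)",
                  x = sprintf("PC1 (%.0f%%)", 100 * emb$explained[1]),
                  y = sprintf("PC2 (%.0f%%)", 100 * emb$explained[2]))
  ggplot2::ggsave("results/figures/nano_pca.pdf", p, width = 5, height = 4)
}
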