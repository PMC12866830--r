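#!/usr/bin/env Rscript
# Segment, filter and classify every simulated field of view.
#
# Reads the localization CSVs written by 01_simulate.R through the package's
# reader (nm -> um conversion), runs Voronoi segmentation, artifact removal,
# background filtering and size classification, and writes per-FOV aggregate
# tables plus the cohort density table used by the downstream statistics.

suppressPackageStartupMessages(library(aggrepaint))

manifest <- read.csv("scratch/sim/manifest.csv")
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

fov_results <- lapply(seq_len(nrow(manifest)), function(i) {
  rec <- manifest[i, ]
  fov <- read_localizations(rec$locs_csv, unit = "nm", extent = c(30, 30),
                            metadata = list(group = rec$group,
                                            replicate = rec$replicate))
  res <- analyze_fov(fov)
  write_aggregates(res$clusters,
                   file.path("results/tables",
                             paste0(rec$fov_id, "_aggregates.csv")))
  list(group = rec$group, replicate = rec$replicate, fov_id = rec$fov_id,
       fov = fov, clusters = res$clusters,
       n_removed_artifact = length(res$removed_artifacts),
       n_removed_background = length(res$removed_background))
})
saveRDS(fov_results, "scratch/fov_results.rds")  # scratch cache for 03/05

cohort <- cohort_table(fov_results)
write.csv(cohort, "results/tables/cohort_densities.csv", row.names = FALSE)
write.csv(replicate_means(cohort), "results/tables/replicate_means.csv",
          row.names = FALSE)
pc <- class_percentages(cohort, level = "group")
write.csv(pc, "results/tables/class_percentages.csv", row.names = FALSE)

nano <- subset(replicate_means(cohort), size_class == "nano")
cat("mean nano-aggregate density per group (um^-2):\n")
print(tapply(nano$density, nano$group, mean))
cat("\nsize-class percentages per group:\n")
print(pc, digits = 3)
cat(sprintf("\nremoved as artifacts: %d; removed as background: %d\n",
            sum(vapply(fov_results, `[[`, numeric(1), "n_removed_artifact")),
            sum(vapply(fov_results, `[[`, numeric(1),
                       "n_removed_background"))))
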