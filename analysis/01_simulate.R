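#!/usr/bin/env Rscript
# Simulate the study's imaging cohorts with known ground truth.
#
# Single-color cohort: four groups of increasing (or, for the
# dephosphorylation-style control, depleted) aggregate burden, each with
# replicates ("tissue sections") holding several 30 x 30 um fields of view.
# The AD-like group's nano-aggregates are drawn with a blob shape and a
# slightly larger characteristic size, emulating the morphological shift the
# dual-stage comparison is meant to detect.
#
# Outputs: per-FOV localization CSVs (nm units, ONI-style header) and
# ground-truth tables under scratch/sim/ (regenerable bulk data).

suppressPackageStartupMessages(library(aggrepaint))

out_dir <- "scratch/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

ad_params <- synth_params(shapes = c(nano = "blob", intermediate = "ellipse",
                                     micro = "fibril"),
                          class_sizes = c(nano = 0.11, intermediate = 0.5,
                                          micro = 1.6))

groups <- list(
  control   = list(n_per_class = c(nano = 3, intermediate = 1, micro = 0)),
  part_like = list(n_per_class = c(nano = 8, intermediate = 2, micro = 1)),
  ad_like   = list(n_per_class = c(nano = 14, intermediate = 4, micro = 2),
                   params = ad_params),
  dephos    = list(n_per_class = c(nano = 1, intermediate = 1, micro = 0))
)

cohort <- generate_cohort(groups, n_fov_per_replicate = 2, n_replicates = 3,
                          rng_seed = 20260919, extent = c(30, 30))

manifest <- do.call(rbind, lapply(cohort, function(rec) {
  loc_path <- file.path(out_dir, paste0(rec$fov_id, "_locs.csv"))
  locs <- rec$fov$locs
  write.csv(data.frame(`Frame` = locs$frame,
                       `X (nm)` = locs$x * 1000,
                       `Y (nm)` = locs$y * 1000,
                       check.names = FALSE),
            loc_path, row.names = FALSE)
  truth_path <- file.path(out_dir, paste0(rec$fov_id, "_truth.csv"))
  write.csv(cbind(rec$truth$aggregates,
                  group = rec$group, replicate = rec$replicate),
            truth_path, row.names = FALSE)
  writeLines(rec$truth$labels,
             file.path(out_dir, paste0(rec$fov_id, "_labels.txt")))
  data.frame(group = rec$group, replicate = rec$replicate,
             fov_id = rec$fov_id, n_locs = nrow(locs),
             n_planted = nrow(rec$truth$aggregates),
             locs_csv = loc_path, truth_csv = truth_path)
}))
write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)

cat(sprintf("simulated %d fields of view (%d groups, %d localizations total)\n",
            nrow(manifest), length(groups), sum(manifest$n_locs)))
cat("per-group planted aggregates per FOV:\n")
print(tapply(manifest$n_planted, manifest$group, mean))
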