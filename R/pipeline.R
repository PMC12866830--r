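# End-to-end composition of the single-color and dual-color pipelines, plus
# ground-truth recovery metrics for validating the pipeline on synthetic
# fields of view.

#' Run the full single-color pipeline on one field of view
#'
#' Segmentation (Voronoi threshold, connectivity, minimum localizations),
#' artifact removal, background filtering and size classification, in that
#' order. Per-stage counts are attached as the `"log"` attribute.
#'
#' @param fov a [new_fov()]
#' @param params [segmentation_params()]
#' @param threshold [background_threshold()]
#' @param artifact_cutoff_k,artifact_min_clusters see [remove_artifacts()]
#' @param verbose print stage counts
#' @return list: `clusters` (kept, classified), `removed_artifacts`,
#'   `removed_background`
#' @export
analyze_fov <- function(fov, params = segmentation_params(),
                        threshold = background_threshold("cy3b"),
                        artifact_cutoff_k = 3, artifact_min_clusters = 10,
                        verbose = FALSE) {
  seg <- segment_fov(fov, params, verbose = verbose)
  art <- suppressWarnings(
    remove_artifacts(seg, cutoff_k = artifact_cutoff_k,
                     min_clusters = artifact_min_clusters))
  bg <- apply_background_filter(art$kept, threshold)
  kept <- assign_size_classes(bg$kept, threshold)
  log <- c(attr(seg, "log"),
           n_after_artifact = length(art$kept),
           n_after_background = length(kept))
  if (verbose)
    message(sprintf("analyze_fov: %d clusters -> %d after artifact -> %d after background",
                    length(seg), length(art$kept), length(kept)))
  structure(list(clusters = kept, removed_artifacts = art$removed,
                 removed_background = bg$removed),
            log = log, class = "fov_analysis")
}

#' Run the dual-color pipeline on a two-channel field of view
#'
#' Merged-reference segmentation, artifact/background filtering and size
#' classification as in the single-color pipeline, followed by the
#' alpha-shape overlap quality control with re-segmentation of low-overlap
#' sub-micro clusters, and enrichment scoring.
#'
#' @param fov_A,fov_B the two channels (or a merged two-channel FOV with
#'   `fov_B = NULL`)
#' @param params [segmentation_params()]
#' @param threshold [background_threshold()] applied to the merged reference
#' @param overlap_cutoff,micro_area_cutoff see [resegment_low_overlap()]
#' @param cutoff singly/dually enrichment cutoff
#' @return list: `clusters`, `records` (an [enrichment_records()] table)
#' @export
analyze_dual_fov <- function(fov_A, fov_B = NULL,
                             params = segmentation_params(),
                             threshold = background_threshold("cy3b"),
                             overlap_cutoff = 30, micro_area_cutoff = 0.15,
                             cutoff = 0.8) {
  merged <- if (is.null(fov_B)) fov_A else merge_fovs(fov_A, fov_B)
  seg <- merge_and_segment(merged, NULL, params)
  art <- suppressWarnings(remove_artifacts(seg))
  bg <- apply_background_filter(art$kept, threshold)
  kept <- assign_size_classes(bg$kept, threshold)
  kept <- resegment_low_overlap(kept, merged, params,
                                overlap_cutoff = overlap_cutoff,
                                micro_area_cutoff = micro_area_cutoff,
                                threshold = threshold)
  # drop re-segmented fragments that fell below the background threshold
  kept <- Filter(function(cl) !is.na(cl$size_class), kept)
  list(clusters = kept, records = enrichment_records(kept, cutoff = cutoff))
}

#' Ground-truth recovery metrics for one synthetic field of view
#'
#' Compares recovered clusters against the generator's planted labels:
#' per-localization label pairs (for external ARI computation), the majority
#' planted label and planted class of every cluster, and the survival of
#' planted noise objects.
#'
#' @param clusters classified aggregates from [analyze_fov()]
#' @param truth the `truth` component of [generate_fov()]
#' @return list: `pairs` (data.frame of recovered/planted labels over
#'   localizations retained in clusters), `cluster_match` (per-cluster
#'   majority planted label, planted class, recovered class, planted
#'   enrichment and recovered score), `noise_surviving` /
#'   `n_noise_planted`
#' @export
recovery_metrics <- function(clusters, truth) {
  pairs <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(recovered = cl$id, planted = truth$labels[cl$members])
  }))
  agg <- truth$aggregates
  cluster_match <- do.call(rbind, lapply(clusters, function(cl) {
    lab <- truth$labels[cl$members]
    maj <- names(sort(table(lab), decreasing = TRUE))[1]
    row <- agg[agg$id == maj, ]
    has_channels <- length(cl$n_per_channel) > 0 && sum(cl$n_per_channel) > 0
    data.frame(
      cluster = cl$id,
      planted = maj,
      purity = mean(lab == maj),
      planted_class = if (nrow(row)) row$target_class else NA_character_,
      recovered_class = cl$size_class,
      planted_enrichment = if (nrow(row)) row$true_enrichment else NA_real_,
      recovered_score = if (has_channels) {
        get_n <- function(ch) {
          v <- cl$n_per_channel[ch]
          if (is.null(v) || is.na(v)) 0L else as.integer(v)
        }
        enrichment_score(get_n("A"), get_n("B"))
      } else NA_real_,
      n_locs = cl$n_locs)
  }))
  planted_noise <- grep("^noise", unique(truth$labels), value = TRUE)
  surviving <- if (is.null(pairs)) character(0)
               else intersect(planted_noise, cluster_match$planted)
  list(pairs = pairs, cluster_match = cluster_match,
       noise_surviving = surviving,
       n_noise_planted = length(planted_noise))
}
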