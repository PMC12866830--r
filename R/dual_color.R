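# Dual-color pipeline: merged-reference segmentation, alpha-shape overlap
# quality control with re-segmentation of spurious merges, and per-aggregate
# enrichment scoring of the two phospho-mark channels.

#' Merge two single-channel fields of view
#'
#' @param fov_A,fov_B [new_fov()] objects sharing the same extent; channels
#'   are stamped `"A"` and `"B"` if unset
#' @return one FOV containing both channels
#' @export
merge_fovs <- function(fov_A, fov_B) {
  stopifnot(inherits(fov_A, "fov"), inherits(fov_B, "fov"))
  if (!isTRUE(all.equal(fov_A$extent, fov_B$extent)))
    stop("input error: the two channels' fields of view have different extents")
  la <- fov_A$locs; lb <- fov_B$locs
  if (all(is.na(la$channel))) la$channel <- rep("A", nrow(la))
  if (all(is.na(lb$channel))) lb$channel <- rep("B", nrow(lb))
  new_fov(rbind(la, lb), fov_A$extent,
          utils::modifyList(fov_A$metadata, list(merged = TRUE)))
}

#' Segment the merged two-channel reference
#'
#' Pools both channels into a reference point cloud and segments it exactly
#' as a single-color image; per-channel member counts are retained on every
#' cluster for the downstream overlap and enrichment steps.
#'
#' @param fov_A,fov_B single-channel FOVs with matching extents (or pass a
#'   pre-merged two-channel FOV as `fov_A` with `fov_B = NULL`)
#' @param params [segmentation_params()]
#' @return list of aggregates with per-channel counts
#' @export
merge_and_segment <- function(fov_A, fov_B = NULL,
                              params = segmentation_params()) {
  merged <- if (is.null(fov_B)) fov_A else merge_fovs(fov_A, fov_B)
  segment_fov(merged, params)
}

# Alpha shape of one channel's members within a cluster; NULL if < 3 points.
channel_shape <- function(cluster, channel, alpha_radius) {
  sel <- which(cluster$channel == channel)
  if (length(sel) < 3) return(NULL)
  alpha_shape(cluster$x[sel], cluster$y[sel], alpha_radius)$contours
}

#' Alpha-shape overlap score of a two-channel cluster
#'
#' Each channel's localizations are turned into an alpha shape; the
#' directional overlap of channel A is the percentage of A's area
#' intersecting B's shape (and vice versa). Both directions are reported;
#' the score used by the re-segmentation gate is their minimum. Clusters
#' with fewer than 3 localizations in either channel get a score of 0 and
#' are flagged.
#'
#' @param cluster an aggregate carrying channel labels
#' @param alpha_radius um; alpha-shape radius
#' @return list with `overlap_A`, `overlap_B` (percent), `score` (their
#'   minimum) and `defined` flag
#' @export
overlap_score <- function(cluster, alpha_radius = 0.05) {
  stopifnot(inherits(cluster, "aggregate"))
  sa <- channel_shape(cluster, "A", alpha_radius)
  sb <- channel_shape(cluster, "B", alpha_radius)
  if (is.null(sa) || is.null(sb))
    return(list(overlap_A = 0, overlap_B = 0, score = 0, defined = FALSE))
  inter <- poly_intersection_area(sa, sb)
  area_a <- polygon_area(sa); area_b <- polygon_area(sb)
  oa <- if (area_a > 0) 100 * inter / area_a else 0
  ob <- if (area_b > 0) 100 * inter / area_b else 0
  oa <- min(oa, 100); ob <- min(ob, 100)
  list(overlap_A = oa, overlap_B = ob, score = min(oa, ob), defined = TRUE)
}

# Re-segment one channel of a cluster with the same density parameters;
# returns a list of member-index subsets (into the cluster's members).
resegment_channel <- function(cluster, channel, extent, params) {
  sel <- which(cluster$channel == channel)
  if (length(sel) < 3) return(if (length(sel)) list(sel) else list())
  sub_fov <- new_fov(data.frame(x = cluster$x[sel], y = cluster$y[sel],
                                frame = 0L, channel = channel),
                     extent)
  sub <- tryCatch(segment_fov(sub_fov, params), error = function(e) list())
  if (length(sub) == 0) return(list(sel))
  parts <- lapply(sub, function(cl) sel[cl$members])
  assigned <- unlist(parts)
  orphans <- setdiff(sel, assigned)
  if (length(orphans)) {
    # keep the partition invariant: attach orphans to the nearest sub-cluster
    cents <- t(vapply(sub, function(cl) cl$centroid, numeric(2)))
    for (o in orphans) {
      dd <- (cents[, 1] - cluster$x[o])^2 + (cents[, 2] - cluster$y[o])^2
      j <- which.min(dd)
      parts[[j]] <- c(parts[[j]], o)
    }
  }
  parts
}

#' Re-segment spuriously merged low-overlap clusters
#'
#' Micro-sized clusters (area above `micro_area_cutoff`) pass through
#' untouched: the area gate is applied first. Smaller clusters whose overlap
#' score is below `overlap_cutoff` are treated as two spatially proximate
#' aggregates fused by the merged reference and are re-segmented per channel
#' with the same parameters; the resulting clusters are re-assigned size
#' classes.
#'
#' @param clusters aggregates from [merge_and_segment()]
#' @param fov the merged FOV (provides the extent for re-segmentation)
#' @param params [segmentation_params()]
#' @param overlap_cutoff percent; clusters scoring below are re-segmented
#' @param micro_area_cutoff um^2; area gate applied before the score gate
#' @param threshold [background_threshold()] for re-classification
#' @return list of aggregates with refreshed ids, classes and `overlap`
#'   fields
#' @export
resegment_low_overlap <- function(clusters, fov,
                                  params = segmentation_params(),
                                  overlap_cutoff = 30,
                                  micro_area_cutoff = 0.15,
                                  threshold = background_threshold("cy3b")) {
  out <- list()
  for (cl in clusters) {
    ov <- if (is.null(cl$overlap)) overlap_score(cl, params$alpha_radius)
          else cl$overlap
    cl$overlap <- ov
    if (cl$area > micro_area_cutoff || ov$score >= overlap_cutoff) {
      out[[length(out) + 1L]] <- cl
      next
    }
    parts <- c(resegment_channel(cl, "A", fov$extent, params),
               resegment_channel(cl, "B", fov$extent, params))
    if (length(parts) <= 1) {  # nothing to split
      out[[length(out) + 1L]] <- cl
      next
    }
    for (p in parts) {
      sub_fov_members <- cl$members[p]
      agg <- as_aggregate(cl$x[p], cl$y[p], cl$channel[p],
                          alpha_radius = params$alpha_radius)
      agg$members <- sub_fov_members
      agg$overlap <- overlap_score(agg, params$alpha_radius)
      agg$resegmented <- TRUE
      out[[length(out) + 1L]] <- agg
    }
  }
  out <- lapply(seq_along(out), function(i) { out[[i]]$id <- i; out[[i]] })
  lapply(out, function(cl) {
    cl$size_class <- if (cl$area >= threshold$area_threshold)
      classify_size(cl$area, threshold) else NA_character_
    cl
  })
}

#' Per-aggregate enrichment score
#'
#' The difference of the two channels' localization counts over their total:
#' `(n_A - n_B) / (n_A + n_B)`. A score of -1 or 1 means the aggregate
#' consists entirely of one phospho-mark; 0 means an equal mix.
#'
#' @param n_A,n_B localization counts per channel (vectorized)
#' @return numeric in \[-1, 1\]
#' @export
enrichment_score <- function(n_A, n_B) {
  stopifnot(length(n_A) == length(n_B), all(n_A >= 0), all(n_B >= 0))
  if (any(n_A + n_B < 1))
    stop("undefined enrichment score: aggregate with zero localizations")
  (n_A - n_B) / (n_A + n_B)
}

#' Classify an enrichment score as singly or dually modified
#'
#' Scores above the cutoff are `SINGLY_A`, below its negative `SINGLY_B`;
#' everything between (boundary inclusive) is `DUALLY`.
#'
#' @param score enrichment scores in \[-1, 1\]
#' @param cutoff default 0.8
#' @return character vector of categories
#' @export
classify_modification <- function(score, cutoff = 0.8) {
  if (any(score < -1 | score > 1))
    stop("input error: enrichment score outside [-1, 1]")
  out <- rep("DUALLY", length(score))
  out[score > cutoff] <- "SINGLY_A"
  out[score < -cutoff] <- "SINGLY_B"
  out
}

#' Enrichment records for a list of two-channel aggregates
#'
#' @param clusters aggregates with per-channel counts
#' @param cutoff singly/dually cutoff on the absolute score
#' @return data.frame: id, n_A, n_B, score, category, size_class
#' @export
enrichment_records <- function(clusters, cutoff = 0.8) {
  get_n <- function(cl, ch) {
    v <- cl$n_per_channel[ch]
    if (is.null(v) || is.na(v)) 0L else as.integer(v)
  }
  n_A <- vapply(clusters, get_n, integer(1), "A")
  n_B <- vapply(clusters, get_n, integer(1), "B")
  score <- enrichment_score(n_A, n_B)
  data.frame(
    id = vapply(clusters, function(cl) as.character(cl$id), character(1)),
    n_A = n_A, n_B = n_B, score = score,
    category = classify_modification(score, cutoff),
    size_class = vapply(clusters, function(cl) cl$size_class, character(1))
  )
}
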