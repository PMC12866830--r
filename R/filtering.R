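# Artifact and background/noise filtering, then area-based classification.
#
# Real aggregates show a positive power-law-like correlation between
# alpha-shape area and localization count; objects far off that trend (tiny
# area with huge counts, or the reverse) are imaging artifacts. Residual
# background objects are removed by a dye-specific area threshold calibrated
# on negative controls, and survivors are classified into three area-based
# size classes.

#' Remove imaging artifacts by a robust area-count trend
#'
#' Fits a robust (least-absolute-deviations) line to log10(localization
#' count) versus log10(area) and removes clusters whose absolute residual
#' exceeds `cutoff_k` times a per-cluster residual scale: the larger of the
#' robust cohort scale (MAD) and the cluster's own Poisson counting noise
#' `1 / (ln(10) * sqrt(n))` on the log10 scale. The counting-noise floor
#' keeps small genuine clusters, whose counts fluctuate by tens of percent,
#' from being flagged when the cohort trend happens to be very tight; a
#' gross artifact (counts tens of times off the trend) is far outside either
#' scale. With fewer than `min_clusters` clusters the trend cannot be
#' estimated and the filter is skipped with a warning.
#'
#' @param clusters list of aggregates
#' @param cutoff_k residual cutoff in residual-scale units
#' @param min_clusters minimum clusters needed to fit the trend
#' @return list with `kept` and `removed` (disjoint, union = input)
#' @export
remove_artifacts <- function(clusters, cutoff_k = 3, min_clusters = 10) {
  if (length(clusters) < min_clusters) {
    warning("artifact filter skipped: only ", length(clusters),
            " clusters (need >= ", min_clusters, ")")
    return(list(kept = clusters, removed = list()))
  }
  n <- vapply(clusters, function(cl) cl$n_locs, numeric(1))
  la <- log10(vapply(clusters, function(cl) cl$area, numeric(1)))
  ln <- log10(n)
  fit <- suppressWarnings(quantreg::rq(ln ~ la, tau = 0.5))
  resid <- as.numeric(stats::residuals(fit))
  scale <- pmax(stats::mad(resid), 1 / (log(10) * sqrt(n)))
  out <- abs(resid) > cutoff_k * scale
  list(kept = clusters[!out], removed = clusters[out])
}

#' Background area threshold
#'
#' Dye-specific defaults (um^2): 0.004 for Cy3b-type imagers, 0.006 for
#' ATTO655-type imagers, which produce slightly more background.
#'
#' @param dye `"cy3b"` or `"atto655"`
#' @param area_threshold explicit um^2 value overriding the dye default
#' @export
background_threshold <- function(dye = c("cy3b", "atto655"),
                                 area_threshold = NULL) {
  dye <- match.arg(dye)
  thr <- if (!is.null(area_threshold)) area_threshold
         else c(cy3b = 0.004, atto655 = 0.006)[[dye]]
  stopifnot(thr > 0)
  structure(list(dye = dye, area_threshold = thr), class = "background_threshold")
}

#' Calibrate the background area threshold
#'
#' `"fixed"` mode returns the dye default. `"percentile"` mode derives the
#' threshold from the area distribution of negative-control clusters: the
#' smallest observed area whose application removes at least `target_removal`
#' of those clusters (keep rule: area >= threshold).
#'
#' @param negative_control_clusters aggregates segmented from a negative
#'   control (required in percentile mode)
#' @param mode `"fixed"` or `"percentile"`
#' @param dye dye label for the fixed default
#' @param target_removal fraction of negative-control objects to remove
#' @return a [background_threshold()]
#' @export
calibrate_background_threshold <- function(negative_control_clusters = NULL,
                                           mode = c("fixed", "percentile"),
                                           dye = "cy3b",
                                           target_removal = 0.97) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(background_threshold(dye))
  if (length(negative_control_clusters) == 0)
    stop("calibration error: percentile mode needs non-empty negative control")
  areas <- sort(vapply(negative_control_clusters, function(cl) cl$area,
                       numeric(1)))
  n <- length(areas)
  k <- ceiling(target_removal * n)  # need at least k areas strictly below
  thr <- if (k < n) areas[k + 1L] else areas[n] * (1 + 1e-9)
  structure(list(dye = dye, area_threshold = thr), class = "background_threshold")
}

#' Apply the background/noise area filter
#'
#' Keeps clusters whose alpha-shape area is at least the threshold
#' (inclusive boundary).
#'
#' @param clusters list of aggregates
#' @param threshold a [background_threshold()]
#' @return list with `kept` and `removed`
#' @export
apply_background_filter <- function(clusters, threshold) {
  stopifnot(inherits(threshold, "background_threshold"))
  keep <- vapply(clusters, function(cl) cl$area >= threshold$area_threshold,
                 logical(1))
  list(kept = clusters[keep], removed = clusters[!keep])
}

#' Area windows of the three size classes
#'
#' Nano: \[background threshold, 0.017) um^2; intermediate: \[0.017, 0.15);
#' micro: \[0.15, Inf). Windows are half-open on the right so the printed
#' shared endpoints (0.017, 0.15) belong to the larger class.
#'
#' @param threshold a [background_threshold()] fixing the lower nano bound
#' @export
size_class_bounds <- function(threshold = background_threshold("cy3b")) {
  c(nano = threshold$area_threshold, intermediate = 0.017, micro = 0.15)
}

#' Classify aggregate areas into size classes
#'
#' @param area numeric vector of alpha-shape areas (um^2); must be at or
#'   above the background threshold (such objects should already have been
#'   filtered)
#' @param threshold a [background_threshold()]
#' @return character vector: `"nano"`, `"intermediate"` or `"micro"`
#' @export
classify_size <- function(area, threshold = background_threshold("cy3b")) {
  b <- size_class_bounds(threshold)
  if (any(area < b[["nano"]]))
    stop("area below the background threshold: object should have been filtered")
  cls <- rep("nano", length(area))
  cls[area >= b[["intermediate"]]] <- "intermediate"
  cls[area >= b[["micro"]]] <- "micro"
  cls
}

#' Assign size classes to a list of aggregates
#'
#' @param clusters list of aggregates (already background-filtered)
#' @param threshold a [background_threshold()]
#' @return the clusters with `size_class` set
#' @export
assign_size_classes <- function(clusters, threshold = background_threshold("cy3b")) {
  lapply(clusters, function(cl) {
    cl$size_class <- classify_size(cl$area, threshold)
    cl
  })
}
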