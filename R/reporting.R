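# Cohort-level summaries and statistics: aggregate densities per unit area,
# size-class and modification percentages, rank-sum group comparisons on
# per-replicate means, and the dual-labeling control analyses.

#' Aggregate density per unit area
#'
#' @param aggregates list of aggregates (or an integer count)
#' @param fov the field of view they came from
#' @return count per um^2
#' @export
density_per_unit_area <- function(aggregates, fov) {
  stopifnot(inherits(fov, "fov"))
  a <- prod(fov$extent)
  if (a <= 0) stop("input error: zero-area field of view")
  n <- if (is.numeric(aggregates)) aggregates else length(aggregates)
  n / a
}

#' Cohort table of per-FOV aggregate counts and densities
#'
#' One row per (group, replicate, FOV, size class) with the aggregate count
#' and density; the sampling hierarchy used for inference is
#' FOV -> replicate mean -> test.
#'
#' @param fov_results list of per-FOV records, each with `group`,
#'   `replicate`, `fov_id`, `fov` and `clusters` (classified aggregates)
#' @return data.frame
#' @export
cohort_table <- function(fov_results) {
  classes <- c("nano", "intermediate", "micro")
  do.call(rbind, lapply(fov_results, function(rec) {
    cls <- vapply(rec$clusters, function(cl) cl$size_class, character(1))
    counts <- vapply(classes, function(k) sum(cls == k, na.rm = TRUE),
                     numeric(1))
    data.frame(group = rec$group, replicate = rec$replicate,
               fov_id = rec$fov_id, size_class = classes,
               count = counts,
               density = counts / prod(rec$fov$extent))
  }))
}

#' Replicate-level mean densities
#'
#' @param cohort a [cohort_table()]
#' @return data.frame of mean density per (group, replicate, size class)
#' @export
replicate_means <- function(cohort) {
  stats::aggregate(density ~ group + replicate + size_class, data = cohort,
                   FUN = mean)
}

#' Size-class percentages per group or replicate
#'
#' Percentages of nano/intermediate/micro aggregates computed from mean
#' counts at the requested level; every row sums to 100. Levels with zero
#' aggregates in all classes are omitted with a message.
#'
#' @param cohort a [cohort_table()]
#' @param level `"group"` or `"replicate"`
#' @return data.frame in wide form with percentage columns per class
#' @export
class_percentages <- function(cohort, level = c("group", "replicate")) {
  level <- match.arg(level)
  f <- stats::as.formula(paste("count ~", level, "+ size_class"))
  m <- stats::aggregate(f, data = cohort, FUN = mean)
  wide <- stats::reshape(m, idvar = level, timevar = "size_class",
                         direction = "wide")
  names(wide) <- sub("^count\\.", "", names(wide))
  for (k in c("nano", "intermediate", "micro"))
    if (!k %in% names(wide)) wide[[k]] <- 0
  tot <- wide$nano + wide$intermediate + wide$micro
  zero <- tot == 0
  if (any(zero)) {
    message("omitting ", sum(zero), " ", level,
            "(s) with zero aggregates in all classes")
    wide <- wide[!zero, ]; tot <- tot[!zero]
  }
  wide$nano <- 100 * wide$nano / tot
  wide$intermediate <- 100 * wide$intermediate / tot
  wide$micro <- 100 * wide$micro / tot
  rownames(wide) <- NULL
  wide[, c(level, "nano", "intermediate", "micro")]
}

#' Singly/dually modification percentages per size class
#'
#' @param records an [enrichment_records()] data.frame, optionally with a
#'   `group` column
#' @param by extra grouping column name (e.g. `"group"`), or `NULL`
#' @return data.frame of percentages of `SINGLY_A` / `SINGLY_B` / `DUALLY`
#'   per size class (and group); rows sum to 100
#' @export
modification_percentages <- function(records, by = NULL) {
  keys <- c(by, "size_class")
  split_keys <- interaction(records[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(records, split_keys), function(r) {
    n <- nrow(r)
    if (n == 0) return(NULL)
    base <- r[1, keys, drop = FALSE]
    base$n <- n
    base$singly_A <- 100 * sum(r$category == "SINGLY_A") / n
    base$singly_B <- 100 * sum(r$category == "SINGLY_B") / n
    base$dually <- 100 * sum(r$category == "DUALLY") / n
    base
  }))
  rownames(out) <- NULL
  out
}

#' Rank-sum comparison of two groups' replicate means
#'
#' Unpaired Wilcoxon rank-sum test on per-replicate means (never per-FOV
#' values). Exact small-sample p-values where possible, normal approximation
#' with tie/continuity correction otherwise. A one-sided variant supports
#' directional hypotheses (e.g. that a treatment decreases aggregate
#' density).
#'
#' @param x,y numeric vectors of per-replicate means (>= 2 each)
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return list with `statistic` (rank-sum W), `p_value`, `alternative`
#' @export
ranksum_compare <- function(x, y, alternative = c("two.sided", "less",
                                                  "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2)
    stop("input error: each group needs at least 2 replicate means")
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       alternative = alternative)
}

#' Correlation of per-channel localization counts across aggregates
#'
#' Dual labeling with steric hindrance between the two antibodies would
#' produce a negative correlation between the two channels' counts; shared
#' aggregate size produces a positive one.
#'
#' @param clusters two-channel aggregates (>= 3)
#' @return list with `pearson`, `spearman`, `n` and a `defined` flag (FALSE
#'   when either channel's counts have zero variance)
#' @export
channel_correlation <- function(clusters) {
  if (length(clusters) < 3)
    stop("input error: need at least 3 aggregates")
  rec <- enrichment_records(clusters, cutoff = 0.8)
  if (stats::sd(rec$n_A) == 0 || stats::sd(rec$n_B) == 0)
    return(list(pearson = NA_real_, spearman = NA_real_, n = nrow(rec),
                defined = FALSE))
  list(pearson = stats::cor(rec$n_A, rec$n_B),
       spearman = stats::cor(rec$n_A, rec$n_B, method = "spearman"),
       n = nrow(rec), defined = TRUE)
}

#' Compare per-aggregate localization counts between run modes
#'
#' Distributional (rank-sum) comparison of per-aggregate localization counts
#' between a single-color and a dual-color run of matched conditions, per
#' size class: a systematic count deficit in the dual-color mode would
#' indicate steric hindrance between the two imager systems.
#'
#' @param single_clusters,dual_clusters classified aggregates from the two
#'   run modes
#' @return data.frame per size class: median counts in both modes and the
#'   two-sided rank-sum p-value; classes absent from either run are omitted
#' @export
single_vs_dual_counts <- function(single_clusters, dual_clusters) {
  tab <- function(cls) data.frame(
    n = vapply(cls, function(cl) cl$n_locs, numeric(1)),
    class = vapply(cls, function(cl) cl$size_class, character(1)))
  s <- tab(single_clusters); d <- tab(dual_clusters)
  classes <- intersect(unique(s$class), unique(d$class))
  out <- do.call(rbind, lapply(classes, function(k) {
    xs <- s$n[s$class == k]; xd <- d$n[d$class == k]
    if (length(xs) < 2 || length(xd) < 2) return(NULL)
    wt <- suppressWarnings(stats::wilcox.test(xs, xd))
    data.frame(size_class = k, median_single = stats::median(xs),
               median_dual = stats::median(xd), n_single = length(xs),
               n_dual = length(xd), p_value = wt$p.value)
  }))
  rownames(out) <- NULL
  out
}
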