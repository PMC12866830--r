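# PCA embedding of descriptor profiles and Jaccard overlap of group
# footprints in the component plane. Groups whose footprints overlap have
# similar morphology; a low Jaccard index marks morphologically distinct
# populations.

#' PCA of descriptor vectors after unit-variance scaling
#'
#' Features are centred and scaled to unit variance; zero-variance features
#' are dropped (with a message) since they carry no shape information and
#' break scaling. Component signs are fixed by making each loading's
#' largest-magnitude entry positive, so the embedding is deterministic.
#'
#' @param descriptors numeric matrix, one row per aggregate
#' @param groups group label per row
#' @return object of class `group_embedding`: `scaling` (means, sds),
#'   `loadings`, `scores`, `explained` (variance fractions), `groups`,
#'   `dropped` feature names
#' @export
run_pca <- function(descriptors, groups = rep("all", nrow(descriptors))) {
  stopifnot(is.matrix(descriptors), nrow(descriptors) == length(groups))
  if (nrow(descriptors) < 2) stop("PCA needs at least 2 observations")
  sds <- apply(descriptors, 2, stats::sd)
  dropped <- colnames(descriptors)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    descriptors <- descriptors[, !(colnames(descriptors) %in% dropped),
                               drop = FALSE]
  }
  pc <- stats::prcomp(descriptors, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  ev <- pc$sdev^2
  structure(list(scaling = list(center = pc$center, scale = pc$scale),
                 loadings = pc$rotation, scores = pc$x,
                 explained = ev / sum(ev), groups = as.character(groups),
                 dropped = dropped),
            class = "group_embedding")
}

#' @export
print.group_embedding <- function(x, ...) {
  cat(sprintf("<group_embedding> %d observations, %d components; PC1-2 explain %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained[1:min(2, length(x$explained))])))
  invisible(x)
}

# Footprint polygon of a 2D score cloud: optional trimming of the most
# extreme points, then an alpha shape with a data-adaptive radius (hull
# fallback for degenerate cases).
score_footprint <- function(px, py, boundary = c("alpha", "hull"),
                            trim = 0.01, alpha = NULL) {
  boundary <- match.arg(boundary)
  if (trim > 0 && length(px) > 10) {
    dc <- sqrt((px - stats::median(px))^2 + (py - stats::median(py))^2)
    keep <- dc <= stats::quantile(dc, 1 - trim)
    px <- px[keep]; py <- py[keep]
  }
  if (boundary == "hull") return(convex_hull_polygon(px, py))
  if (is.null(alpha)) {
    nn <- FNN::get.knn(cbind(px, py), k = 1)$nn.dist[, 1]
    alpha <- max(3 * stats::median(nn), .Machine$double.eps)
  }
  shp <- alpha_shape(px, py, alpha)
  shp$contours
}

#' Jaccard overlap of two groups' footprints in a component plane
#'
#' Projects each group's scores onto the requested component plane, builds a
#' footprint polygon per group, and returns the Jaccard index
#' (intersection area over union area; `method = "sum"` divides by the
#' summed footprint areas instead).
#'
#' @param embedding a [run_pca()] result
#' @param pair character length-2, the two group labels (defaults to the
#'   first two groups present)
#' @param plane integer length-2, component indices (default PC1-PC2)
#' @param boundary footprint construction, `"alpha"` (default) or `"hull"`
#' @param trim fraction of extreme points removed per group before building
#'   the footprint
#' @param method `"union"` or `"sum"`, see [polygon_jaccard()]
#' @param alpha optional fixed alpha radius in score units
#' @return list with `pair`, `plane`, `polygons` and `jaccard`
#' @export
group_overlap_jaccard <- function(embedding, pair = NULL, plane = c(1, 2),
                                  boundary = c("alpha", "hull"), trim = 0.01,
                                  method = c("union", "sum"), alpha = NULL) {
  stopifnot(inherits(embedding, "group_embedding"))
  boundary <- match.arg(boundary); method <- match.arg(method)
  if (is.null(pair)) pair <- unique(embedding$groups)[1:2]
  stopifnot(length(pair) == 2)
  polys <- lapply(pair, function(g) {
    sel <- embedding$groups == g
    if (sum(sel) < 3)
      stop("group '", g, "' has fewer than 3 observations in the plane")
    score_footprint(embedding$scores[sel, plane[1]],
                    embedding$scores[sel, plane[2]],
                    boundary = boundary, trim = trim, alpha = alpha)
  })
  list(pair = pair, plane = plane, polygons = polys,
       jaccard = polygon_jaccard(polys[[1]], polys[[2]], method = method))
}

#' Pairwise Jaccard overlap table for all groups
#'
#' @inheritParams group_overlap_jaccard
#' @return data.frame with columns `group1`, `group2`, `jaccard`
#' @export
pairwise_group_overlap <- function(embedding, plane = c(1, 2), ...) {
  gs <- unique(embedding$groups)
  pairs <- utils::combn(gs, 2)
  data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    jaccard = apply(pairs, 2, function(p)
      group_overlap_jaccard(embedding, pair = p, plane = plane, ...)$jaccard))
}
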