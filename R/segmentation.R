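# Voronoi-tessellation density segmentation.
#
# Each localization gets a Voronoi cell; the cell area is an inverse density
# proxy, so localizations in dense regions (small cells) are retained by an
# area threshold and grouped into clusters along shared Voronoi edges
# (equivalently, Delaunay edges between retained localizations). Clusters
# with fewer than `min_locs` members are discarded, and each surviving
# cluster receives an alpha-shape boundary and area.

#' Segmentation parameters
#'
#' @param voronoi_area_threshold um^2; localizations whose bounded Voronoi
#'   cell area is at most this are considered dense. Burden-dependent in
#'   practice (low-burden tissue 0.00018-0.0003 um^2, higher-burden 0.001 up
#'   to beyond 0.002 um^2); the default is the top of the low-burden range.
#' @param min_locs minimum localizations per cluster (inclusive)
#' @param alpha_radius um; alpha-shape radius for cluster boundaries
#' @export
segmentation_params <- function(voronoi_area_threshold = 3e-4, min_locs = 10,
                                alpha_radius = 0.05) {
  stopifnot(voronoi_area_threshold > 0, min_locs > 0, alpha_radius > 0)
  structure(list(voronoi_area_threshold = voronoi_area_threshold,
                 min_locs = as.integer(min_locs),
                 alpha_radius = alpha_radius),
            class = "segmentation_params")
}

#' Voronoi tessellation of a field of view
#'
#' Computes one Voronoi cell per localization, clipped to the FOV rectangle.
#' Cells touching the FOV boundary have no well-defined (unclipped) area and
#' are flagged unbounded; downstream thresholding treats them as failing the
#' density criterion. Adjacency (shared Voronoi edge) is returned as the
#' Delaunay edge list.
#'
#' @param fov a [new_fov()] object with at least 3 non-collinear localizations
#' @return object of class `voronoi_tessellation`: `area` (um^2 per cell),
#'   `bounded` (logical), `edges` (2-column index matrix), `n`
#' @export
compute_voronoi <- function(fov) {
  stopifnot(inherits(fov, "fov"))
  x <- fov$locs$x; y <- fov$locs$y
  n <- length(x)
  if (n < 3) stop("degenerate input: need at least 3 localizations")
  cross <- abs((x[2] - x[1]) * (y - y[1]) - (x - x[1]) * (y[2] - y[1]))
  if (max(cross) < 1e-12 * max(1, diff(range(x)), diff(range(y))))
    stop("degenerate input: all localizations are collinear")
  tm <- tryCatch(interp::tri.mesh(x, y, duplicate = "error"),
                 error = function(e)
                   stop("tessellation failed (duplicate or degenerate ",
                        "localizations): ", conditionMessage(e)))
  tr <- interp::triangles(tm)
  i1 <- tr[, "node1"]; i2 <- tr[, "node2"]; i3 <- tr[, "node3"]
  # orient counter-clockwise
  cr <- (x[i2] - x[i1]) * (y[i3] - y[i1]) - (x[i3] - x[i1]) * (y[i2] - y[i1])
  flip <- cr < 0
  tmp <- i2[flip]; i2[flip] <- i3[flip]; i3[flip] <- tmp
  # circumcenters (vectorized)
  ax <- x[i1]; ay <- y[i1]; bx <- x[i2]; by <- y[i2]; cx <- x[i3]; cy <- y[i3]
  d2 <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d2
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d2
  # Each triangle contributes to each vertex's Voronoi cell the signed quad
  # (p, m1, circumcenter, m2) where m1/m2 are the midpoints of the two edges
  # at p. Midpoints lie on the bisector segments joining neighbouring
  # circumcenters, so the signed quads telescope to the exact dual-cell area
  # (correct also for obtuse triangles whose circumcenter lies outside).
  quad_area <- function(px, py, m1x, m1y, m2x, m2y) {
    ((m1x - px) * (uy - py) - (ux - px) * (m1y - py) +
       (ux - px) * (m2y - py) - (m2x - px) * (uy - py)) / 2
  }
  m12x <- (ax + bx) / 2; m12y <- (ay + by) / 2
  m23x <- (bx + cx) / 2; m23y <- (by + cy) / 2
  m31x <- (cx + ax) / 2; m31y <- (cy + ay) / 2
  contrib <- c(quad_area(ax, ay, m12x, m12y, m31x, m31y),
               quad_area(bx, by, m23x, m23y, m12x, m12y),
               quad_area(cx, cy, m31x, m31y, m23x, m23y))
  area <- as.numeric(rowsum(contrib, c(i1, i2, i3), reorder = TRUE))
  ids <- sort(unique(c(i1, i2, i3)))
  full_area <- rep(NA_real_, n)
  full_area[ids] <- area
  bounded <- rep(TRUE, n)
  bounded[interp::on.convex.hull(tm, x, y)] <- FALSE  # hull cells unbounded
  bounded[!is.finite(full_area) | full_area <= 0] <- FALSE
  ef <- c(i1, i2, i3); et <- c(i2, i3, i1)
  ekey <- pmin(ef, et) * (n + 1) + pmax(ef, et)
  keep <- !duplicated(ekey)
  edges <- cbind(pmin(ef, et)[keep], pmax(ef, et)[keep])
  structure(list(area = full_area, bounded = bounded, edges = edges, n = n),
            class = "voronoi_tessellation")
}

# Build one aggregate object from member indices of a FOV.
make_aggregate <- function(id, members, fov, alpha_radius) {
  x <- fov$locs$x[members]; y <- fov$locs$y[members]
  ch <- fov$locs$channel[members]
  shp <- alpha_shape(x, y, alpha_radius)
  counts <- if (all(is.na(ch))) integer(0) else table(factor(ch))
  structure(list(
    id = id,
    members = members,
    x = x, y = y,
    channel = ch,
    n_locs = length(members),
    n_per_channel = counts,
    boundary = shp$contours,
    triangles = shp$triangles,
    area = shp$area,
    perimeter = shp$perimeter,
    centroid = c(mean(x), mean(y)),
    size_class = NA_character_
  ), class = "aggregate")
}

#' @export
print.aggregate <- function(x, ...) {
  cat(sprintf("<aggregate %s> %d locs, area %.4g um^2, class %s\n",
              x$id, x$n_locs, x$area, x$size_class))
  invisible(x)
}

#' Threshold Voronoi cells and cluster dense localizations
#'
#' Retains localizations whose Voronoi cell is bounded with area at most the
#' threshold (inclusive), then takes connected components of the tessellation
#' adjacency restricted to retained localizations as candidate clusters.
#'
#' @param fov the field of view the tessellation came from
#' @param tess a [compute_voronoi()] tessellation
#' @param params [segmentation_params()]
#' @return list of aggregate objects (possibly empty)
#' @export
threshold_and_cluster <- function(fov, tess, params = segmentation_params()) {
  stopifnot(inherits(tess, "voronoi_tessellation"),
            inherits(params, "segmentation_params"))
  retained <- tess$bounded & tess$area <= params$voronoi_area_threshold
  idx <- which(retained)
  if (length(idx) == 0) return(list())
  keep_edge <- retained[tess$edges[, 1]] & retained[tess$edges[, 2]]
  g <- igraph::graph_from_edgelist(
    matrix(match(tess$edges[keep_edge, ], idx), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  split_members <- split(idx, comp)
  lapply(seq_along(split_members), function(i) {
    make_aggregate(i, sort(split_members[[i]]), fov, params$alpha_radius)
  })
}

#' Discard clusters with too few localizations
#'
#' Clusters with fewer than `min_locs` members (default 10) are discarded;
#' the bound is inclusive, so a 10-member cluster survives.
#'
#' @param clusters list of aggregates
#' @param min_locs minimum member count
#' @export
filter_min_locs <- function(clusters, min_locs = 10) {
  Filter(function(cl) cl$n_locs >= min_locs, clusters)
}

#' Segment a field of view into candidate aggregates
#'
#' Composite of [compute_voronoi()], [threshold_and_cluster()] and
#' [filter_min_locs()]. Stage counts are recorded in the `"log"` attribute
#' and printed when `verbose = TRUE`.
#'
#' @param fov a [new_fov()] object
#' @param params [segmentation_params()]
#' @param verbose print per-stage counts
#' @return list of aggregates with sequential ids
#' @export
segment_fov <- function(fov, params = segmentation_params(), verbose = FALSE) {
  tess <- compute_voronoi(fov)
  clusters <- threshold_and_cluster(fov, tess, params)
  kept <- filter_min_locs(clusters, params$min_locs)
  kept <- lapply(seq_along(kept), function(i) { kept[[i]]$id <- i; kept[[i]] })
  log <- c(n_locs = nrow(fov$locs),
           n_retained = sum(tess$bounded & tess$area <= params$voronoi_area_threshold),
           n_clusters = length(clusters),
           n_after_min_locs = length(kept))
  if (verbose)
    message(sprintf("segment_fov: %d locs -> %d dense -> %d clusters -> %d after min_locs",
                    log[1], log[2], log[3], log[4]))
  attr(kept, "log") <- log
  kept
}

#' Tabulate a list of aggregates
#'
#' @param clusters list of aggregate objects
#' @return data.frame with id, per-channel counts, area, class and (when
#'   present) enrichment score / category / overlap score
#' @export
aggregate_table <- function(clusters) {
  if (length(clusters) == 0) {
    return(data.frame(id = integer(0), n_locs = integer(0), n_A = integer(0),
                      n_B = integer(0), area = numeric(0),
                      size_class = character(0),
                      enrichment = numeric(0), category = character(0)))
  }
  chans <- sort(unique(unlist(lapply(clusters, function(cl) names(cl$n_per_channel)))))
  count_for <- function(cl, ch) {
    v <- cl$n_per_channel[ch]
    if (is.null(v) || is.na(v)) 0L else as.integer(v)
  }
  data.frame(
    id = vapply(clusters, function(cl) cl$id, numeric(1)),
    n_locs = vapply(clusters, function(cl) cl$n_locs, numeric(1)),
    n_A = if (length(chans) >= 1) vapply(clusters, count_for, integer(1), chans[1]) else 0L,
    n_B = if (length(chans) >= 2) vapply(clusters, count_for, integer(1), chans[2]) else 0L,
    area = vapply(clusters, function(cl) cl$area, numeric(1)),
    size_class = vapply(clusters, function(cl) cl$size_class, character(1)),
    enrichment = vapply(clusters, function(cl)
      if (is.null(cl$enrichment)) NA_real_ else cl$enrichment, numeric(1)),
    category = vapply(clusters, function(cl)
      if (is.null(cl$category)) NA_character_ else cl$category, character(1))
  )
}
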