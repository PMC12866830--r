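# Polygon and alpha-shape utilities shared by segmentation, morphology and the
# dual-color overlap scoring. Polygons are represented in the polyclip
# convention: a list of contours, each a list(x = numeric, y = numeric).
# Outer boundaries are counter-clockwise, holes clockwise, so signed shoelace
# areas sum to the net enclosed area.

#' Signed area of a single polygon contour (shoelace formula)
#' @param contour list with numeric `x` and `y`
#' @return signed area; positive for counter-clockwise orientation
#' @keywords internal
contour_signed_area <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Net area of a polygon (list of oriented contours, holes negative)
#' @param poly list of contours
#' @export
polygon_area <- function(poly) {
  if (length(poly) == 0) return(0)
  abs(sum(vapply(poly, contour_signed_area, numeric(1))))
}

contour_perimeter <- function(contour) {
  x <- contour$x; y <- contour$y
  n <- length(x)
  if (n < 2) return(0)
  j <- c(seq(2, n), 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}

polygon_perimeter <- function(poly) {
  sum(vapply(poly, contour_perimeter, numeric(1)))
}

#' Area of the intersection of two polygons
#' @keywords internal
poly_intersection_area <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(0)
  polygon_area(polyclip::polyclip(a, b, op = "intersection",
                                  fillA = "nonzero", fillB = "nonzero"))
}

#' Area of the union of two polygons
#' @keywords internal
poly_union_area <- function(a, b) {
  if (length(a) == 0) return(polygon_area(b))
  if (length(b) == 0) return(polygon_area(a))
  polygon_area(polyclip::polyclip(a, b, op = "union",
                                  fillA = "nonzero", fillB = "nonzero"))
}

#' Jaccard index of two polygons
#'
#' Intersection-over-union of two polygonal regions. The `"sum"` method
#' divides the intersection by the summed areas of the two polygons instead of
#' by the union (a stricter score, bounded by 1/2 for disjoint-interior
#' polygons of equal area).
#'
#' @param a,b polygons as lists of contours (`list(list(x=, y=))`)
#' @param method `"union"` (default, the standard Jaccard index) or `"sum"`
#' @return numeric in \[0, 1\]
#' @export
polygon_jaccard <- function(a, b, method = c("union", "sum")) {
  method <- match.arg(method)
  inter <- poly_intersection_area(a, b)
  denom <- if (method == "union") poly_union_area(a, b)
           else polygon_area(a) + polygon_area(b)
  if (denom <= 0) return(0)
  inter / denom
}

#' Convex hull of a point set as an oriented polygon
#' @keywords internal
convex_hull_polygon <- function(x, y) {
  idx <- grDevices::chull(x, y)
  ctr <- list(x = x[idx], y = y[idx])
  if (contour_signed_area(ctr) < 0) ctr <- list(x = rev(ctr$x), y = rev(ctr$y))
  list(ctr)
}

tri_circumradius <- function(ax, ay, bx, by, cx, cy) {
  a <- sqrt((bx - cx)^2 + (by - cy)^2)
  b <- sqrt((ax - cx)^2 + (ay - cy)^2)
  ccc <- sqrt((ax - bx)^2 + (ay - by)^2)
  area2 <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))  # 2 * area
  r <- a * b * ccc / (2 * area2)
  r[area2 < .Machine$double.eps] <- Inf
  r
}

tri_area <- function(ax, ay, bx, by, cx, cy) {
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

#' Alpha shape of a 2D point set
#'
#' Builds the alpha complex from the Delaunay triangulation: triangles whose
#' circumradius is at most `alpha` are kept; the shape's area is the summed
#' triangle area, its boundary the set of edges belonging to exactly one kept
#' triangle, traced into oriented closed contours (outer boundaries
#' counter-clockwise, holes clockwise). When no triangle survives the filter
#' (or the triangulation is degenerate) the convex hull is used as a fallback
#' so small dense clusters always receive a boundary.
#'
#' @param x,y point coordinates (micrometres)
#' @param alpha alpha radius (micrometres): maximum circumradius of a kept
#'   Delaunay triangle
#' @param fallback_hull if `TRUE` (default) fall back to the convex hull when
#'   the alpha complex is empty or the triangulation degenerate
#' @return object of class `alpha_shape`: list with `contours`, `area`,
#'   `perimeter`, `triangles` (index matrix into the input points),
#'   `used_hull` flag
#' @export
alpha_shape <- function(x, y, alpha, fallback_hull = TRUE) {
  stopifnot(length(x) == length(y), alpha > 0)
  hull_result <- function() {
    if (!fallback_hull) stop("degenerate alpha shape and hull fallback disabled")
    poly <- convex_hull_polygon(x, y)
    structure(list(contours = poly, area = polygon_area(poly),
                   perimeter = polygon_perimeter(poly),
                   triangles = matrix(integer(0), ncol = 3), used_hull = TRUE),
              class = "alpha_shape")
  }
  if (length(x) < 3) return(hull_result())
  tm <- tryCatch(interp::tri.mesh(x, y, duplicate = "remove"),
                 error = function(e) NULL)
  if (is.null(tm)) return(hull_result())
  tr <- interp::triangles(tm)
  # map back to original indices if duplicates were removed
  ox <- tm$x; oy <- tm$y
  remap <- match(paste(ox, oy), paste(x, y))
  i1 <- remap[tr[, "node1"]]; i2 <- remap[tr[, "node2"]]; i3 <- remap[tr[, "node3"]]
  r <- tri_circumradius(x[i1], y[i1], x[i2], y[i2], x[i3], y[i3])
  keep <- is.finite(r) & r <= alpha
  if (!any(keep)) return(hull_result())
  i1 <- i1[keep]; i2 <- i2[keep]; i3 <- i3[keep]
  # orient every triangle counter-clockwise so directed boundary edges come
  # out with consistent winding (outer CCW, holes CW)
  cross <- (x[i2] - x[i1]) * (y[i3] - y[i1]) - (x[i3] - x[i1]) * (y[i2] - y[i1])
  flip <- cross < 0
  tmp <- i2[flip]; i2[flip] <- i3[flip]; i3[flip] <- tmp
  area <- sum(tri_area(x[i1], y[i1], x[i2], y[i2], x[i3], y[i3]))
  edges_from <- c(i1, i2, i3)
  edges_to <- c(i2, i3, i1)
  keys <- paste(edges_from, edges_to)
  rev_keys <- paste(edges_to, edges_from)
  boundary <- !(keys %in% rev_keys)  # boundary iff the reversed edge is absent
  bf <- edges_from[boundary]; bt <- edges_to[boundary]
  contours <- trace_boundary_cycles(bf, bt, x, y)
  perim <- sum(sqrt((x[bt] - x[bf])^2 + (y[bt] - y[bf])^2))
  structure(list(contours = contours, area = area, perimeter = perim,
                 triangles = cbind(i1, i2, i3), used_hull = FALSE),
            class = "alpha_shape")
}

# Chain directed boundary edges (from -> to) into closed oriented contours.
trace_boundary_cycles <- function(from, to, x, y) {
  if (length(from) == 0) return(list())
  out_edges <- split(seq_along(from), from)
  used <- rep(FALSE, length(from))
  contours <- list()
  for (start in seq_along(from)) {
    if (used[start]) next
    cycle <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      cycle <- c(cycle, from[e])
      nxt_candidates <- out_edges[[as.character(to[e])]]
      nxt_candidates <- nxt_candidates[!used[nxt_candidates]]
      if (length(nxt_candidates) == 0) break
      e <- nxt_candidates[1]
    }
    if (length(cycle) >= 3) {
      contours[[length(contours) + 1L]] <- list(x = x[cycle], y = y[cycle])
    }
  }
  contours
}

#' Centroid (area-weighted) of a polygon, falling back to the vertex mean
#' @keywords internal
polygon_centroid <- function(poly) {
  ctr <- poly[[which.max(abs(vapply(poly, contour_signed_area, numeric(1))))]]
  x <- ctr$x; y <- ctr$y
  n <- length(x)
  j <- c(seq(2, n), 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}
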