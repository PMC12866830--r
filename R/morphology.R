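# 67-descriptor morphological profile of an aggregate's raw point cloud.
#
# Descriptors are computed from the localizations themselves (no rendering):
# point/density statistics from the raw coordinates, geometric and boundary
# descriptors from the alpha-shape polygon, skeleton descriptors from a
# thinned raster of that polygon, fractal/heterogeneity measures from
# box-counting and gliding-box statistics, and composite shape indices.
# The registry order is fixed; every vector has exactly 67 finite entries
# for clusters with at least 10 localizations and non-degenerate geometry.

descriptor_families <- list(
  point = c("n_locs", "loc_density", "nn_dist_mean", "nn_dist_sd",
            "nn_dist_min", "nn_dist_max", "centroid_dist_mean",
            "centroid_dist_sd"),
  geometric = c("area", "perimeter", "circularity", "equiv_diameter",
                "major_axis", "minor_axis", "aspect_ratio", "eccentricity",
                "orientation", "hull_area", "hull_perimeter", "solidity",
                "convexity", "extent", "bbox_width", "bbox_height"),
  moment = c("hu1", "hu2", "hu3", "hu4", "hu5", "hu6", "hu7",
             "radius_gyration", "mu20", "mu02", "mu11", "moment_anisotropy"),
  boundary = c("radial_mean", "radial_sd", "radial_min", "radial_max",
               "radial_cv", "curv_mean", "curv_sd", "curv_max", "curv_min",
               "bending_energy", "curv_zero_crossings", "boundary_vertices"),
  skeleton = c("skel_length", "skel_branches", "skel_branch_points",
               "skel_endpoints", "skel_branch_len_mean", "skel_branch_len_max",
               "skel_tortuosity", "skel_area_ratio", "skel_longest_path",
               "skel_cycles"),
  fractal = c("boundary_boxdim", "cloud_boxdim", "corr_dim", "lacunarity"),
  composite = c("elongation", "compactness", "norm_radius_gyration",
                "voronoi_cell_area_mean", "voronoi_cell_area_cv")
)

#' The fixed descriptor registry
#'
#' @return character vector of the 67 descriptor names in registry order,
#'   with a `"family"` attribute giving each descriptor's family
#' @export
descriptor_registry <- function() {
  nm <- unlist(descriptor_families, use.names = FALSE)
  attr(nm, "family") <- rep(names(descriptor_families),
                            times = lengths(descriptor_families))
  nm
}

#' Build a standalone aggregate from raw coordinates
#'
#' Convenience constructor for descriptor computation and tests: wraps a
#' point cloud into the same aggregate structure [segment_fov()] produces.
#'
#' @param x,y coordinates, um
#' @param channel optional per-point channel labels
#' @param alpha_radius um; alpha-shape radius for the boundary
#' @param id aggregate id
#' @export
as_aggregate <- function(x, y, channel = NULL, alpha_radius = 0.05, id = 1) {
  stopifnot(length(x) == length(y))
  ch <- if (is.null(channel)) rep(NA_character_, length(x)) else channel
  shp <- alpha_shape(x, y, alpha_radius)
  structure(list(
    id = id, members = seq_along(x), x = x, y = y, channel = ch,
    n_locs = length(x),
    n_per_channel = if (all(is.na(ch))) integer(0) else table(factor(ch)),
    boundary = shp$contours, triangles = shp$triangles,
    area = shp$area, perimeter = shp$perimeter,
    centroid = c(mean(x), mean(y)), size_class = NA_character_
  ), class = "aggregate")
}

# Resample a closed contour to m points equally spaced in arc length.
resample_contour <- function(contour, m = 128) {
  x <- c(contour$x, contour$x[1]); y <- c(contour$y, contour$y[1])
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  t <- seq(0, total, length.out = m + 1)[seq_len(m)]
  xi <- stats::approx(s, x, xout = t, ties = "ordered")$y
  yi <- stats::approx(s, y, xout = t, ties = "ordered")$y
  list(x = xi, y = yi, h = total / m)
}

# Curvature of a closed, arc-length-uniform contour by central differences.
closed_curvature <- function(rc) {
  x <- rc$x; y <- rc$y; h <- rc$h
  ip <- c(2:length(x), 1L); im <- c(length(x), 1:(length(x) - 1L))
  dx <- (x[ip] - x[im]) / (2 * h); dy <- (y[ip] - y[im]) / (2 * h)
  ddx <- (x[ip] - 2 * x + x[im]) / h^2; ddy <- (y[ip] - 2 * y + y[im]) / h^2
  sp <- (dx^2 + dy^2)^1.5
  k <- (dx * ddy - dy * ddx) / pmax(sp, .Machine$double.eps)
  k
}

# Even-odd point-in-polygon over a list of contours (holes handled by parity).
points_in_contours <- function(px, py, contours) {
  inside <- integer(length(px))
  for (ctr in contours) {
    w <- polyclip::pointinpolygon(list(x = px, y = py), ctr)
    inside <- inside + as.integer(w != 0)
  }
  inside %% 2L == 1L
}

# Rasterize alpha-shape contours on a grid anchored at the shape's bbox.
rasterize_contours <- function(contours, grid_n = 64) {
  allx <- unlist(lapply(contours, `[[`, "x"))
  ally <- unlist(lapply(contours, `[[`, "y"))
  w <- max(allx) - min(allx); h <- max(ally) - min(ally)
  px <- max(w, h) / grid_n
  if (px <= 0) return(NULL)
  nx <- max(2L, ceiling(w / px)); ny <- max(2L, ceiling(h / px))
  cx <- min(allx) + (seq_len(nx) - 0.5) * px
  cy <- min(ally) + (seq_len(ny) - 0.5) * px
  gx <- rep(cx, times = ny); gy <- rep(cy, each = nx)
  mask <- matrix(points_in_contours(gx, gy, contours), nrow = nx, ncol = ny)
  list(mask = mask, pixel = px)
}

# Zhang-Suen thinning of a binary matrix.
zhang_suen_thin <- function(m) {
  pad <- function(a) {
    out <- matrix(FALSE, nrow(a) + 2, ncol(a) + 2)
    out[2:(nrow(a) + 1), 2:(ncol(a) + 1)] <- a
    out
  }
  p <- pad(m)
  nr <- nrow(p); nc <- ncol(p)
  sh <- function(a, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- a[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      n2 <- sh(p, -1, 0); n3 <- sh(p, -1, 1); n4 <- sh(p, 0, 1)
      n5 <- sh(p, 1, 1);  n6 <- sh(p, 1, 0);  n7 <- sh(p, 1, -1)
      n8 <- sh(p, 0, -1); n9 <- sh(p, -1, -1)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (!n2 & n3) + (!n3 & n4) + (!n4 & n5) + (!n5 & n6) +
        (!n6 & n7) + (!n7 & n8) + (!n8 & n9) + (!n9 & n2)
      cond <- p & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & !(n2 & n4 & n6) & !(n4 & n6 & n8)
      } else {
        cond <- cond & !(n2 & n4 & n8) & !(n2 & n6 & n8)
      }
      if (any(cond)) { p[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  p[2:(nr - 1), 2:(nc - 1)]
}

# Skeleton metrics from a thinned raster (pixel units scaled by pixel size).
skeleton_metrics <- function(mask, pixel, area) {
  skel <- zhang_suen_thin(mask)
  pix <- which(skel, arr.ind = TRUE)
  s <- nrow(pix)
  out <- c(skel_length = 0, skel_branches = 0, skel_branch_points = 0,
           skel_endpoints = 0, skel_branch_len_mean = 0,
           skel_branch_len_max = 0, skel_tortuosity = 1,
           skel_area_ratio = 0, skel_longest_path = 0, skel_cycles = 0)
  if (s < 2) return(out)
  key <- pix[, 1] + nrow(skel) * (pix[, 2] - 1L)
  idx <- seq_len(s)
  on_map <- rep(NA_integer_, nrow(skel) * ncol(skel))
  on_map[key] <- idx
  get_at <- function(dr, dc) {
    r <- pix[, 1] + dr; c <- pix[, 2] + dc
    ok <- r >= 1 & r <= nrow(skel) & c >= 1 & c <= ncol(skel)
    nb <- rep(NA_integer_, s)
    nb[ok] <- on_map[r[ok] + nrow(skel) * (c[ok] - 1L)]
    nb
  }
  e_from <- integer(0); e_to <- integer(0); e_w <- numeric(0)
  for (off in list(c(0, 1), c(1, 0))) {
    nb <- get_at(off[1], off[2])
    ok <- !is.na(nb)
    e_from <- c(e_from, idx[ok]); e_to <- c(e_to, nb[ok])
    e_w <- c(e_w, rep(1, sum(ok)))
  }
  # diagonals, pruned when an orthogonal neighbour shortcuts them
  for (off in list(c(1, 1), c(1, -1))) {
    nb <- get_at(off[1], off[2])
    o1 <- get_at(off[1], 0); o2 <- get_at(0, off[2])
    ok <- !is.na(nb) & is.na(o1) & is.na(o2)
    e_from <- c(e_from, idx[ok]); e_to <- c(e_to, nb[ok])
    e_w <- c(e_w, rep(sqrt(2), sum(ok)))
  }
  if (length(e_from) == 0) return(out)
  g <- igraph::graph_from_edgelist(cbind(e_from, e_to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, s - igraph::vcount(g)))
  igraph::E(g)$weight <- e_w
  deg <- igraph::degree(g)
  total_len <- sum(e_w) * pixel
  n_comp <- igraph::components(g)$no
  endpoints <- which(deg == 1)
  branch_pts <- which(deg >= 3)
  sub <- igraph::delete_vertices(g, branch_pts)
  sub_comp <- igraph::components(sub)
  n_branches <- sub_comp$no
  # branch lengths: edge-weight totals per component of the pruned graph
  memb <- sub_comp$membership
  if (igraph::ecount(sub) > 0) {
    el <- igraph::as_edgelist(sub, names = FALSE)
    bl <- tapply(igraph::E(sub)$weight, memb[el[, 1]], sum) * pixel
  } else bl <- numeric(0)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  d[!is.finite(d)] <- 0
  longest <- max(d) * pixel
  tort <- if (length(endpoints) >= 2) {
    ec <- pix[endpoints, , drop = FALSE] * pixel
    span <- max(stats::dist(ec))
    if (span > 0) total_len / span else 1
  } else 1
  out["skel_length"] <- total_len
  out["skel_branches"] <- n_branches
  out["skel_branch_points"] <- length(branch_pts)
  out["skel_endpoints"] <- length(endpoints)
  out["skel_branch_len_mean"] <- if (length(bl)) mean(bl) else 0
  out["skel_branch_len_max"] <- if (length(bl)) max(bl) else 0
  out["skel_tortuosity"] <- tort
  out["skel_area_ratio"] <- total_len / area
  out["skel_longest_path"] <- longest
  out["skel_cycles"] <- length(e_from) - s + n_comp
  out
}

box_count_dim <- function(x, y, scales = 2^(2:5)) {
  w <- max(max(x) - min(x), max(y) - min(y))
  if (w <= 0) return(0)
  counts <- vapply(scales, function(k) {
    eps <- w / k
    length(unique(paste(floor((x - min(x)) / eps),
                        floor((y - min(y)) / eps))))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(scales)))[[2]]
}

correlation_dim <- function(x, y, max_points = 600) {
  n <- length(x)
  if (n > max_points) {
    keep <- unique(as.integer(round(seq(1, n, length.out = max_points))))
    x <- x[keep]; y <- y[keep]
  }
  d <- as.numeric(stats::dist(cbind(x, y)))
  d <- d[d > 0]
  if (length(d) < 10) return(0)
  r1 <- stats::quantile(d, 0.10); r2 <- stats::quantile(d, 0.40)
  if (r2 <= r1) return(0)
  c1 <- mean(d <= r1); c2 <- mean(d <= r2)
  if (c1 <= 0) return(0)
  (log(c2) - log(c1)) / (log(r2) - log(r1))
}

gliding_box_lacunarity <- function(mask, box = NULL) {
  nx <- nrow(mask); ny <- ncol(mask)
  if (is.null(box)) box <- max(2L, min(nx, ny) %/% 4L)
  if (box > min(nx, ny)) box <- min(nx, ny)
  cs <- apply(apply(mask * 1, 2, cumsum), 1, cumsum)  # transposed cumsum2d
  cs <- t(cs)
  sum2d <- function(i, j) {  # mass of box with lower corner (i, j)
    i2 <- i + box - 1L; j2 <- j + box - 1L
    cs[i2, j2] -
      (if (i > 1) cs[i - 1L, j2] else 0) -
      (if (j > 1) cs[i2, j - 1L] else 0) +
      (if (i > 1 && j > 1) cs[i - 1L, j - 1L] else 0)
  }
  is <- seq_len(nx - box + 1L); js <- seq_len(ny - box + 1L)
  masses <- as.numeric(vapply(js, function(j)
    vapply(is, function(i) sum2d(i, j), numeric(1)), numeric(length(is))))
  m <- mean(masses)
  if (m <= 0) return(0)
  stats::var(masses) * (length(masses) - 1) / length(masses) / m^2 + 1
}

#' Compute the 67-descriptor morphological profile of one aggregate
#'
#' @param cluster an aggregate (from [segment_fov()] or [as_aggregate()])
#'   with at least 10 member localizations
#' @param grid_n raster resolution (pixels along the longer bbox side) for
#'   skeleton and lacunarity descriptors; the grid is anchored to the
#'   shape's bounding box, so descriptors are translation invariant
#' @param boundary_samples number of arc-length-uniform samples of the
#'   boundary used for radial and curvature descriptors
#' @return named numeric vector of length 67 in registry order
#' @export
compute_descriptors <- function(cluster, grid_n = 64, boundary_samples = 128) {
  stopifnot(inherits(cluster, "aggregate"))
  if (cluster$n_locs < 10)
    stop("descriptors need >= 10 localizations, got ", cluster$n_locs)
  x <- cluster$x; y <- cluster$y
  n <- cluster$n_locs
  area <- cluster$area; perim <- cluster$perimeter
  if (!is.finite(area) || area <= 0 || perim <= 0)
    stop("descriptor error in geometric family: degenerate boundary ",
         "(collinear or coincident localizations)")
  d <- stats::setNames(numeric(67), descriptor_registry())

  # --- point / density ---
  nn <- FNN::get.knn(cbind(x, y), k = 1)$nn.dist[, 1]
  cx <- mean(x); cy <- mean(y)
  dc <- sqrt((x - cx)^2 + (y - cy)^2)
  d["n_locs"] <- n
  d["loc_density"] <- n / area
  d["nn_dist_mean"] <- mean(nn); d["nn_dist_sd"] <- stats::sd(nn)
  d["nn_dist_min"] <- min(nn); d["nn_dist_max"] <- max(nn)
  d["centroid_dist_mean"] <- mean(dc); d["centroid_dist_sd"] <- stats::sd(dc)

  # --- geometric ---
  cv <- stats::cov(cbind(x, y)) * (n - 1) / n
  ev <- eigen(cv, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  major <- 4 * sqrt(lam[1]); minor <- 4 * sqrt(lam[2])
  if (minor <= 0)
    stop("descriptor error in geometric family: zero minor axis (collinear points)")
  hull <- convex_hull_polygon(x, y)
  bbw <- max(x) - min(x); bbh <- max(y) - min(y)
  d["area"] <- area; d["perimeter"] <- perim
  d["circularity"] <- 4 * pi * area / perim^2
  d["equiv_diameter"] <- 2 * sqrt(area / pi)
  d["major_axis"] <- major; d["minor_axis"] <- minor
  d["aspect_ratio"] <- major / minor
  d["eccentricity"] <- sqrt(max(0, 1 - (minor / major)^2))
  d["orientation"] <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) %% pi
  d["hull_area"] <- polygon_area(hull)
  d["hull_perimeter"] <- polygon_perimeter(hull)
  d["solidity"] <- area / max(d["hull_area"], .Machine$double.eps)
  d["convexity"] <- d["hull_perimeter"] / perim
  d["extent"] <- area / max(bbw * bbh, .Machine$double.eps)
  d["bbox_width"] <- bbw; d["bbox_height"] <- bbh

  # --- moments ---
  # Point-cloud central moments. The Hu set is normalized by the alpha-shape
  # area as the size measure (eta_pq = mu_pq / (n * A^((p+q)/2))), which
  # makes it dimensionless and invariant under uniform dilation; the pixel
  # convention (normalizing by mu00 = area in pixels) has no analogue for a
  # fixed-size point sample.
  xc <- x - cx; yc <- y - cy
  mu <- function(p, q) sum(xc^p * yc^q)
  eta <- function(p, q) mu(p, q) / (n * area^((p + q) / 2))
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  d["hu1"] <- e20 + e02
  d["hu2"] <- (e20 - e02)^2 + 4 * e11^2
  d["hu3"] <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  d["hu4"] <- (e30 + e12)^2 + (e21 + e03)^2
  d["hu5"] <- (e30 - 3 * e12) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
    (3 * e21 - e03) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  d["hu6"] <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
    4 * e11 * (e30 + e12) * (e21 + e03)
  d["hu7"] <- (3 * e21 - e03) * (e30 + e12) *
    ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
    (e30 - 3 * e12) * (e21 + e03) * (3 * (e30 + e12)^2 - (e21 + e03)^2)
  d["radius_gyration"] <- sqrt(mean(dc^2))
  d["mu20"] <- mu(2, 0) / n; d["mu02"] <- mu(0, 2) / n
  d["mu11"] <- mu(1, 1) / n
  d["moment_anisotropy"] <- (lam[1] - lam[2]) / max(lam[1] + lam[2],
                                                    .Machine$double.eps)

  # --- boundary (longest contour, arc-length resampled) ---
  main_i <- which.max(vapply(cluster$boundary, function(c)
    abs(contour_signed_area(c)), numeric(1)))
  main <- cluster$boundary[[main_i]]
  pc <- polygon_centroid(cluster$boundary)
  rc <- resample_contour(main, boundary_samples)
  rad <- sqrt((rc$x - pc[1])^2 + (rc$y - pc[2])^2)
  k <- closed_curvature(rc)
  sk <- sign(k); sk[sk == 0] <- 1
  d["radial_mean"] <- mean(rad); d["radial_sd"] <- stats::sd(rad)
  d["radial_min"] <- min(rad); d["radial_max"] <- max(rad)
  d["radial_cv"] <- stats::sd(rad) / max(mean(rad), .Machine$double.eps)
  d["curv_mean"] <- mean(k); d["curv_sd"] <- stats::sd(k)
  d["curv_max"] <- max(k); d["curv_min"] <- min(k)
  d["bending_energy"] <- sum(k^2) * rc$h
  d["curv_zero_crossings"] <- sum(sk != sk[c(2:length(sk), 1)])
  d["boundary_vertices"] <- sum(vapply(cluster$boundary, function(c)
    length(c$x), numeric(1)))

  # --- skeleton ---
  ras <- rasterize_contours(cluster$boundary, grid_n)
  if (is.null(ras) || !any(ras$mask)) {
    skm <- c(skel_length = 0, skel_branches = 0, skel_branch_points = 0,
             skel_endpoints = 0, skel_branch_len_mean = 0,
             skel_branch_len_max = 0, skel_tortuosity = 1,
             skel_area_ratio = 0, skel_longest_path = 0, skel_cycles = 0)
  } else {
    skm <- skeleton_metrics(ras$mask, ras$pixel, area)
  }
  d[names(skm)] <- skm

  # --- fractal / heterogeneity ---
  d["boundary_boxdim"] <- box_count_dim(rc$x, rc$y)
  d["cloud_boxdim"] <- box_count_dim(x, y)
  d["corr_dim"] <- correlation_dim(x, y)
  d["lacunarity"] <- if (is.null(ras)) 0 else gliding_box_lacunarity(ras$mask)

  # --- composite ---
  d["elongation"] <- 1 - minor / major
  d["compactness"] <- d["equiv_diameter"] / major
  d["norm_radius_gyration"] <- d["radius_gyration"] / sqrt(area / pi)
  vc <- tryCatch({
    pad <- 0.05 * max(bbw, bbh, 1e-6)
    dd <- deldir::deldir(x, y, rw = c(min(x) - pad, max(x) + pad,
                                      min(y) - pad, max(y) + pad))
    ar <- dd$summary$dir.area
    # interior cells only: drop those clipped by the padded window
    clip <- dd$dirsgs$bp1 | dd$dirsgs$bp2
    edge_cells <- unique(c(dd$dirsgs$ind1[clip], dd$dirsgs$ind2[clip]))
    ar_in <- if (length(edge_cells) < length(ar)) ar[-edge_cells] else ar
    c(mean(ar_in), stats::sd(ar_in) / max(mean(ar_in), .Machine$double.eps))
  }, error = function(e) c(area / n, 0.53))
  d["voronoi_cell_area_mean"] <- vc[1]
  d["voronoi_cell_area_cv"] <- if (is.finite(vc[2])) vc[2] else 0.53

  if (any(!is.finite(d))) {
    bad <- names(d)[!is.finite(d)][1]
    fam <- attr(descriptor_registry(), "family")[match(bad, descriptor_registry())]
    stop("descriptor error in ", fam, " family: non-finite '", bad, "'")
  }
  d
}

#' Descriptor matrix for a list of aggregates
#'
#' @param clusters list of aggregates
#' @param ... forwarded to [compute_descriptors()]
#' @return numeric matrix, one row per aggregate, 67 registry columns
#' @export
compute_descriptor_matrix <- function(clusters, ...) {
  out <- t(vapply(clusters, compute_descriptors, numeric(67), ...))
  rownames(out) <- vapply(clusters, function(cl) as.character(cl$id),
                          character(1))
  out
}

#' Per-group summaries of selected descriptors
#'
#' Summaries mirror figure-style panels: per-group distributions and
#' per-replicate means of named descriptors, log10-transformed where
#' requested (circularity, major axis and area are typically displayed on a
#' log10 scale).
#'
#' @param descriptors matrix from [compute_descriptor_matrix()]
#' @param groups group label per aggregate (row)
#' @param features descriptor names to summarize
#' @param replicates optional replicate label per aggregate
#' @param log10_features subset of `features` to log10-transform
#' @return list with `values` (long per-aggregate table), `group_summary`
#'   and, when replicates are given, `replicate_means`
#' @export
descriptor_summaries <- function(descriptors, groups, features,
                                 replicates = NULL,
                                 log10_features = intersect(
                                   features,
                                   c("circularity", "major_axis", "area"))) {
  unknown <- setdiff(features, colnames(descriptors))
  if (length(unknown))
    stop("unknown descriptor name(s): ", paste(unknown, collapse = ", "))
  stopifnot(length(groups) == nrow(descriptors))
  long <- do.call(rbind, lapply(features, function(f) {
    v <- descriptors[, f]
    if (f %in% log10_features) v <- log10(v)
    data.frame(feature = f, group = groups,
               replicate = if (is.null(replicates)) NA_character_ else replicates,
               value = as.numeric(v))
  }))
  gs <- stats::aggregate(value ~ feature + group, data = long,
                         FUN = function(v) c(mean = mean(v),
                                             median = stats::median(v),
                                             sd = if (length(v) > 1) stats::sd(v) else 0))
  gs <- cbind(gs[c("feature", "group")], as.data.frame(gs$value))
  out <- list(values = long, group_summary = gs)
  if (!is.null(replicates)) {
    out$replicate_means <- stats::aggregate(value ~ feature + group + replicate,
                                            data = long, FUN = mean)
  }
  out
}
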