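# Fixture builders and independent oracles used across the suite.

# Uniform points in a disc.
disc_points <- function(n, r = 0.1, center = c(0, 0), seed = NULL) {
  draw <- function() {
    rr <- r * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    data.frame(x = center[1] + rr * cos(th), y = center[2] + rr * sin(th))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Minimal aggregate stub for filter/classification tests that only need
# counts, areas and channel tallies.
fake_cluster <- function(area, n_locs = 100, id = 1, size_class = NA_character_,
                         n_A = NA, n_B = NA) {
  npc <- if (is.na(n_A)) integer(0) else {
    v <- c(A = as.integer(n_A), B = as.integer(n_B))
    as.table(v)
  }
  structure(list(id = id, members = seq_len(n_locs), x = numeric(n_locs),
                 y = numeric(n_locs), channel = rep(NA_character_, n_locs),
                 n_locs = n_locs, n_per_channel = npc,
                 boundary = list(), triangles = matrix(integer(0), ncol = 3),
                 area = area, perimeter = 2 * sqrt(pi * area),
                 centroid = c(0, 0), size_class = size_class),
            class = "aggregate")
}

# Axis-aligned square as a polyclip-style polygon.
square_poly <- function(x0, y0, side) {
  list(list(x = c(x0, x0 + side, x0 + side, x0),
            y = c(y0, y0, y0 + side, y0 + side)))
}

# Exhaustive connected-components search over the retained-localization
# adjacency graph (breadth-first), independent of igraph.
bfs_components <- function(retained_idx, edges) {
  keep <- edges[, 1] %in% retained_idx & edges[, 2] %in% retained_idx
  adj <- list()
  for (i in retained_idx) adj[[as.character(i)]] <- integer(0)
  if (any(keep)) {
    for (r in which(keep)) {
      a <- edges[r, 1]; b <- edges[r, 2]
      adj[[as.character(a)]] <- c(adj[[as.character(a)]], b)
      adj[[as.character(b)]] <- c(adj[[as.character(b)]], a)
    }
  }
  seen <- character(0)
  comps <- list()
  for (i in retained_idx) {
    if (as.character(i) %in% seen) next
    queue <- i; comp <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (as.character(v) %in% seen) next
      seen <- c(seen, as.character(v))
      comp <- c(comp, v)
      queue <- c(queue, adj[[as.character(v)]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# Brute-force Delaunay edges: (i, j, k) is a Delaunay triangle iff no other
# point lies strictly inside its circumcircle. O(n^4); for tiny n only.
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), ncol = 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    others <- setdiff(1:n, c(i, j, k))
    if (all((x[others] - ux)^2 + (y[others] - uy)^2 > r2 * (1 + 1e-12))) {
      edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
    }
  }
  unique(t(apply(edges, 1, sort)))
}

# Monte-Carlo Voronoi cell areas: fraction of a fine grid nearest each site.
grid_voronoi_areas <- function(x, y, extent, n_grid = 400) {
  gx <- (seq_len(n_grid) - 0.5) * extent[1] / n_grid
  gy <- (seq_len(n_grid) - 0.5) * extent[2] / n_grid
  grid <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  nn <- FNN::get.knnx(cbind(x, y), grid, k = 1)$nn.index[, 1]
  tabulate(nn, nbins = length(x)) * prod(extent) / n_grid^2
}

# Exact two-sided rank-sum p-value by enumeration over all rank assignments
# (no ties assumed).
enum_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  Us <- apply(sets, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(Us <= W), mean(Us >= W)))
}

# Canonical form of a clustering (list of member-index vectors) for
# set-equality comparison.
canonical_partition <- function(member_list) {
  sets <- lapply(member_list, function(m) paste(sort(m), collapse = ","))
  sort(unlist(sets))
}
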