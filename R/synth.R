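# Synthetic localization-data generator with planted ground truth.
#
# Fields of view contain planted aggregates of three size classes (nano
# ~90 nm diameter discs, intermediate ~500 nm major-axis ellipses, micro
# ~1.6 um fibril-like chains), a uniform background, and sparse sub-threshold
# noise clusters mimicking the behaviour of negative-control samples (puncta
# smaller than real aggregates, fewer than 10 localizations). Localization
# counts scale linearly with planted area (DNA-PAINT localization counts
# scale with the number of targets), and every localization carries a
# ground-truth label so segmentation, filtering, classification and
# enrichment recovery can be validated exactly.

#' Tunable generator parameters
#'
#' @param loc_density localizations per um^2 of planted shape area
#' @param jitter_sigma um; isotropic Gaussian localization jitter (typical
#'   DNA-PAINT localization precision)
#' @param size_cv lognormal coefficient of variation of characteristic sizes
#'   around the class means
#' @param class_sizes um; mean characteristic size per class (diameter for
#'   discs, major axis otherwise)
#' @param shapes shape kind per class: `disc`, `ellipse`, `fibril` or `blob`
#' @param ellipse_aspect major/minor axis ratio for ellipse shapes
#' @param fibril_width_frac fibril width as a fraction of its length
#' @param min_separation um; minimum distance between planted centers
#' @param margin um; keep-out border inside the FOV
#' @param max_attempts placement attempts before giving up
#' @export
synth_params <- function(loc_density = 20000, jitter_sigma = 0.01,
                         size_cv = 0.08,
                         class_sizes = c(nano = 0.09, intermediate = 0.5,
                                         micro = 1.6),
                         shapes = c(nano = "disc", intermediate = "ellipse",
                                    micro = "fibril"),
                         ellipse_aspect = 2, fibril_width_frac = 0.1875,
                         min_separation = 3, margin = 2,
                         max_attempts = 5000) {
  structure(as.list(environment()), class = "synth_params")
}

#' Noise model for background and spurious puncta
#'
#' Uniform background localizations plus small noise clusters whose
#' localization counts stay strictly below the minimum-localization filter
#' and whose areas stay below the background area threshold, so the filtering
#' stages remove them by construction.
#'
#' @param uniform_rate background localizations per um^2
#' @param cluster_rate noise clusters per um^2
#' @param cluster_locs integer support for per-cluster localization counts
#'   (strictly below 10 by default)
#' @param cluster_diameter um; diameter of the disc a noise cluster occupies
#' @export
noise_model <- function(uniform_rate = 5, cluster_rate = 0.02,
                        cluster_locs = 3:8, cluster_diameter = 0.05) {
  stopifnot(uniform_rate >= 0, cluster_rate >= 0, all(cluster_locs >= 1))
  structure(list(uniform_rate = uniform_rate, cluster_rate = cluster_rate,
                 cluster_locs = as.integer(cluster_locs),
                 cluster_diameter = cluster_diameter),
            class = "noise_model")
}

#' Two-channel composition mixture for planted aggregates
#'
#' Channel fractions are drawn from a three-part mixture: pure channel A
#' (fraction 1), pure channel B (fraction 0), or a dually modified Beta
#' component centred on balanced composition.
#'
#' @param p_singly_A,p_singly_B probabilities of channel-pure aggregates
#' @param dual_shape1,dual_shape2 Beta parameters of the dual component
#' @export
enrichment_mix <- function(p_singly_A = 0.2, p_singly_B = 0.2,
                           dual_shape1 = 6, dual_shape2 = 6) {
  stopifnot(p_singly_A + p_singly_B <= 1)
  structure(list(p_singly_A = p_singly_A, p_singly_B = p_singly_B,
                 dual_shape1 = dual_shape1, dual_shape2 = dual_shape2),
            class = "enrichment_mix")
}

sample_channel_fractions <- function(mix, n) {
  u <- stats::runif(n)
  frac <- stats::rbeta(n, mix$dual_shape1, mix$dual_shape2)
  frac[u < mix$p_singly_A] <- 1
  frac[u >= mix$p_singly_A & u < mix$p_singly_A + mix$p_singly_B] <- 0
  frac
}

#' Specification of one planted aggregate
#'
#' @param center length-2 numeric, um
#' @param shape `"disc"`, `"ellipse"`, `"fibril"` or `"blob"`
#' @param target_class `"nano"`, `"intermediate"` or `"micro"`
#' @param characteristic_size um; disc diameter or major-axis length
#' @param n_locs number of localizations to draw
#' @param channel_fraction fraction of localizations assigned to channel A;
#'   the planted enrichment is `2 * channel_fraction - 1`
#' @param angle orientation (radians) for anisotropic shapes
#' @param aspect major/minor ratio for ellipses
#' @param width_frac width fraction for fibrils
#' @export
planted_aggregate <- function(center, shape, target_class, characteristic_size,
                              n_locs, channel_fraction = 1, angle = 0,
                              aspect = 2, width_frac = 0.1875) {
  stopifnot(n_locs >= 1, characteristic_size > 0,
            channel_fraction >= 0, channel_fraction <= 1)
  structure(list(center = center, shape = shape, target_class = target_class,
                 characteristic_size = characteristic_size,
                 n_locs = as.integer(n_locs),
                 channel_fraction = channel_fraction,
                 true_enrichment = 2 * channel_fraction - 1,
                 angle = angle, aspect = aspect, width_frac = width_frac),
            class = "planted_aggregate")
}

# Area of a planted shape's support, um^2 (used to scale n_locs with size).
shape_support_area <- function(shape, size, aspect = 2, width_frac = 0.1875) {
  switch(shape,
         disc = pi * (size / 2)^2,
         ellipse = pi * (size / 2) * (size / (2 * aspect)),
         fibril = size * (size * width_frac),
         blob = pi * (size / 2)^2,
         stop("unknown shape kind: ", shape))
}

# Draw points uniformly inside a planted shape (before jitter), centred at 0.
sample_shape_points <- function(spec, n) {
  s <- spec$characteristic_size
  rot <- function(px, py, a) cbind(px * cos(a) - py * sin(a),
                                   px * sin(a) + py * cos(a))
  switch(spec$shape,
    disc = {
      r <- (s / 2) * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    },
    ellipse = {
      r <- sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      rot(r * cos(th) * s / 2, r * sin(th) * s / (2 * spec$aspect), spec$angle)
    },
    fibril = {
      k <- 8L
      step <- s / k
      dirs <- spec$angle + cumsum(c(0, stats::rnorm(k - 1, 0, 0.35)))
      vx <- cumsum(c(0, step * cos(dirs)))
      vy <- cumsum(c(0, step * sin(dirs)))
      vx <- vx - (min(vx) + max(vx)) / 2
      vy <- vy - (min(vy) + max(vy)) / 2
      t <- stats::runif(n, 0, s)
      seg <- pmin(floor(t / step) + 1L, k)
      frac <- t / step - (seg - 1L)
      px <- vx[seg] + frac * (vx[seg + 1L] - vx[seg])
      py <- vy[seg] + frac * (vy[seg + 1L] - vy[seg])
      w <- s * spec$width_frac
      nx <- -(vy[seg + 1L] - vy[seg]) / step
      ny <- (vx[seg + 1L] - vx[seg]) / step
      off <- stats::runif(n, -w / 2, w / 2)
      cbind(px + off * nx, py + off * ny)
    },
    blob = {
      ak <- stats::runif(3, 0.05, 0.25) / (2:4)
      ph <- stats::runif(3, 0, 2 * pi)
      rmax <- (s / 2) * (1 + sum(ak))
      out <- matrix(numeric(0), ncol = 2)
      while (nrow(out) < n) {
        m <- 2 * (n - nrow(out)) + 16
        r <- rmax * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        rb <- (s / 2) * (1 + ak[1] * cos(2 * th + ph[1]) +
                           ak[2] * cos(3 * th + ph[2]) +
                           ak[3] * cos(4 * th + ph[3]))
        ok <- r <= rb
        out <- rbind(out, cbind(r[ok] * cos(th[ok]), r[ok] * sin(th[ok])))
      }
      out[seq_len(n), , drop = FALSE]
    },
    stop("unknown shape kind: ", spec$shape)
  )
}

#' Sample the localizations of one planted aggregate
#'
#' Points are drawn uniformly within the planted shape, perturbed by
#' isotropic Gaussian jitter, and assigned to channel A as an exact count
#' `round(channel_fraction * n_locs)` at randomly chosen positions (so the
#' realized composition matches the planted enrichment up to 1/n).
#'
#' @param spec a [planted_aggregate()]
#' @param jitter_sigma um; localization jitter scale (>= 0)
#' @param rng_seed optional integer; when given the draw is deterministic
#' @return data.frame with `x`, `y`, `channel`
#' @export
sample_aggregate <- function(spec, jitter_sigma = 0.01, rng_seed = NULL) {
  stopifnot(inherits(spec, "planted_aggregate"), jitter_sigma >= 0)
  draw <- function() {
    n <- spec$n_locs
    pts <- sample_shape_points(spec, n)
    pts <- pts + matrix(stats::rnorm(2 * n, 0, jitter_sigma), ncol = 2)
    n_A <- round(spec$channel_fraction * n)
    channel <- rep("B", n)
    channel[sample.int(n, n_A)] <- "A"
    data.frame(x = pts[, 1] + spec$center[1],
               y = pts[, 2] + spec$center[2],
               channel = channel)
  }
  if (is.null(rng_seed)) draw() else withr::with_seed(rng_seed, draw())
}

# Rejection-place centers with a minimum pairwise separation inside margins.
place_centers <- function(k, extent, margin, min_sep, max_attempts) {
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0
  while (length(cx) < k) {
    attempts <- attempts + 1
    if (attempts > max_attempts)
      stop("placement error: could not place ", k,
           " aggregates at separation ", min_sep)
    px <- stats::runif(1, margin, extent[1] - margin)
    py <- stats::runif(1, margin, extent[2] - margin)
    if (length(cx) == 0 || min((cx - px)^2 + (cy - py)^2) >= min_sep^2) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  cbind(cx, cy)
}

# Frames compatible with a channel's laser blocks under a frame-block program.
sample_channel_frames <- function(channel, program, n) {
  k <- length(program$channel_order)
  ci <- match(channel, program$channel_order) - 1L
  n_blocks <- program$total_frames %/% program$block_length
  own_blocks <- ci + k * (0:(ceiling(n_blocks / k) - 1L))
  own_blocks <- own_blocks[own_blocks < n_blocks]
  b <- own_blocks[sample.int(length(own_blocks), n, replace = TRUE)]
  as.integer(b * program$block_length +
               sample.int(program$block_length, n, replace = TRUE) - 1L)
}

#' Generate one field of view with ground truth
#'
#' @param n_per_class named counts of planted aggregates,
#'   `c(nano=, intermediate=, micro=)`
#' @param noise a [noise_model()]
#' @param extent FOV width/height, um
#' @param mix an [enrichment_mix()] for two-channel FOVs, or `NULL` for a
#'   single-color FOV (no channel labels)
#' @param rng_seed integer seed; the FOV is fully deterministic given it
#' @param params [synth_params()]
#' @param program [channel_program()] used to stamp channel-consistent frame
#'   indices on two-channel FOVs
#' @param metadata named list forwarded to the FOV
#' @return list with `fov` (a [new_fov()]) and `truth`: per-localization
#'   `labels` (`"agg<k>"`, `"noise<j>"` or `"bg"`) and an `aggregates`
#'   data.frame of planted parameters including `true_enrichment`
#' @export
generate_fov <- function(n_per_class = c(nano = 12, intermediate = 5, micro = 2),
                         noise = noise_model(), extent = c(50, 50),
                         mix = NULL, rng_seed = 1,
                         params = synth_params(),
                         program = channel_program(),
                         metadata = list()) {
  stopifnot(all(extent > 0))
  withr::with_seed(rng_seed, {
    classes <- rep(names(n_per_class), times = n_per_class)
    k <- length(classes)
    centers <- if (k > 0)
      place_centers(k, extent, params$margin, params$min_separation,
                    params$max_attempts)
    else matrix(numeric(0), ncol = 2)
    fracs <- if (is.null(mix)) rep(1, k) else sample_channel_fractions(mix, k)
    specs <- vector("list", k)
    loc_list <- vector("list", k)
    for (i in seq_len(k)) {
      cls <- classes[i]
      size <- params$class_sizes[[cls]] *
        stats::rlnorm(1, -params$size_cv^2 / 2, params$size_cv)
      shape <- params$shapes[[cls]]
      area <- shape_support_area(shape, size, params$ellipse_aspect,
                                 params$fibril_width_frac)
      n_locs <- max(10L, as.integer(round(params$loc_density * area)))
      specs[[i]] <- planted_aggregate(
        center = centers[i, ], shape = shape, target_class = cls,
        characteristic_size = size, n_locs = n_locs,
        channel_fraction = fracs[i],
        angle = stats::runif(1, 0, pi),
        aspect = params$ellipse_aspect, width_frac = params$fibril_width_frac)
      loc_list[[i]] <- sample_aggregate(specs[[i]], params$jitter_sigma)
    }
    # noise clusters: < 10 localizations each, sub-threshold footprint
    n_nc <- stats::rpois(1, noise$cluster_rate * prod(extent))
    nc_list <- vector("list", n_nc)
    if (n_nc > 0) {
      nc_centers <- cbind(stats::runif(n_nc, 0, extent[1]),
                          stats::runif(n_nc, 0, extent[2]))
      for (j in seq_len(n_nc)) {
        m <- noise$cluster_locs[sample.int(length(noise$cluster_locs), 1)]
        r <- (noise$cluster_diameter / 2) * sqrt(stats::runif(m))
        th <- stats::runif(m, 0, 2 * pi)
        nc_list[[j]] <- data.frame(
          x = nc_centers[j, 1] + r * cos(th),
          y = nc_centers[j, 2] + r * sin(th),
          channel = if (is.null(mix)) NA_character_
                    else sample(c("A", "B"), m, replace = TRUE))
      }
    }
    # uniform background
    n_bg <- stats::rpois(1, noise$uniform_rate * prod(extent))
    bg <- data.frame(x = stats::runif(n_bg, 0, extent[1]),
                     y = stats::runif(n_bg, 0, extent[2]),
                     channel = if (is.null(mix)) rep(NA_character_, n_bg)
                               else sample(c("A", "B"), n_bg, replace = TRUE))
    locs <- rbind(do.call(rbind, loc_list), do.call(rbind, nc_list), bg)
    if (!is.null(locs) && nrow(locs) > 0 && is.null(mix))
      locs$channel <- NA_character_  # single-color: no channel labels
    agg_labels <- if (k > 0)
      rep(paste0("agg", seq_len(k)),
          times = vapply(specs, function(s) s$n_locs, integer(1)))
    else character(0)
    noise_labels <- if (n_nc > 0)
      rep(paste0("noise", seq_len(n_nc)),
          times = vapply(nc_list, nrow, integer(1)))
    else character(0)
    labels <- c(agg_labels, noise_labels, rep("bg", n_bg))
    if (is.null(locs) || nrow(locs) == 0)
      locs <- data.frame(x = numeric(0), y = numeric(0),
                         channel = character(0))
    # clamp jittered points into the FOV (moves only extreme tails)
    locs$x <- pmin(pmax(locs$x, 0), extent[1])
    locs$y <- pmin(pmax(locs$y, 0), extent[2])
    locs$frame <- if (is.null(mix) || nrow(locs) == 0) {
      if (nrow(locs) == 0) integer(0)
      else sample.int(program$total_frames, nrow(locs), replace = TRUE) - 1L
    } else {
      fr <- integer(nrow(locs))
      for (ch in unique(locs$channel)) {
        sel <- which(locs$channel == ch)
        fr[sel] <- sample_channel_frames(ch, program, length(sel))
      }
      fr
    }
    truth <- list(
      labels = labels,
      aggregates = if (k > 0) data.frame(
        id = paste0("agg", seq_len(k)),
        x = centers[, 1], y = centers[, 2],
        shape = vapply(specs, function(s) s$shape, character(1)),
        target_class = classes,
        characteristic_size = vapply(specs, function(s) s$characteristic_size,
                                     numeric(1)),
        n_locs = vapply(specs, function(s) s$n_locs, integer(1)),
        channel_fraction = fracs,
        true_enrichment = 2 * fracs - 1
      ) else data.frame(),
      n_noise_clusters = n_nc
    )
    list(fov = new_fov(locs, extent, metadata), truth = truth)
  })
}

#' Generate a hierarchical cohort of fields of view
#'
#' Mirrors the case/replicate/FOV sampling hierarchy of a tissue-imaging
#' study: each group has replicates (tissue sections), each replicate several
#' fields of view. Per-FOV seeds are derived deterministically from the
#' master seed.
#'
#' @param groups named list of group specifications; each may override
#'   `n_per_class`, `mix`, `noise`, `params`
#' @param n_fov_per_replicate,n_replicates hierarchy sizes
#' @param rng_seed master seed
#' @param ... defaults forwarded to [generate_fov()]
#' @return list of per-FOV records: `fov`, `truth`, `group`, `replicate`,
#'   `fov_id`
#' @export
generate_cohort <- function(groups, n_fov_per_replicate = 4, n_replicates = 4,
                            rng_seed = 1, ...) {
  defaults <- list(...)
  total <- length(groups) * n_replicates * n_fov_per_replicate
  seeds <- withr::with_seed(rng_seed,
                            sample.int(.Machine$integer.max - 1L, total))
  out <- vector("list", total)
  i <- 0
  for (g in names(groups)) {
    spec <- groups[[g]]
    for (r in seq_len(n_replicates)) {
      for (f in seq_len(n_fov_per_replicate)) {
        i <- i + 1
        args <- utils::modifyList(defaults, spec)
        args$rng_seed <- seeds[i]
        args$metadata <- list(group = g, replicate = paste0(g, "_rep", r),
                              fov_id = paste0(g, "_rep", r, "_fov", f))
        rec <- do.call(generate_fov, args)
        out[[i]] <- list(fov = rec$fov, truth = rec$truth, group = g,
                         replicate = paste0(g, "_rep", r),
                         fov_id = paste0(g, "_rep", r, "_fov", f))
      }
    }
  }
  out
}

#' Generate a field of view of adjacent channel-pure disc pairs
#'
#' A focused scenario for dual-color quality control: each planted object is
#' a pair of channel-pure discs whose facing edges almost touch, so the
#' merged-reference segmentation fuses the pair into one cluster whose
#' per-channel alpha shapes barely overlap (a spurious merge the overlap
#' score should flag and re-segmentation should split).
#'
#' @param n_pairs number of planted pairs
#' @param disc_diameter um; diameter of each disc
#' @param gap um; edge-to-edge gap between paired discs
#' @param extent FOV size, um
#' @param rng_seed integer seed
#' @param params [synth_params()] (density and jitter are used)
#' @return list with `fov` and `truth` (`labels` like `"pair<k>_A"`)
#' @export
generate_blob_pair_fov <- function(n_pairs = 6, disc_diameter = 0.2,
                                   gap = 0.02, extent = c(30, 30),
                                   rng_seed = 1, params = synth_params()) {
  withr::with_seed(rng_seed, {
    centers <- place_centers(n_pairs, extent, params$margin,
                             params$min_separation, params$max_attempts)
    n_locs <- max(10L, as.integer(round(
      params$loc_density * pi * (disc_diameter / 2)^2)))
    loc_list <- list(); labels <- character(0)
    for (i in seq_len(n_pairs)) {
      ang <- stats::runif(1, 0, 2 * pi)
      off <- (disc_diameter + gap) / 2
      for (side in c("A", "B")) {
        sgn <- if (side == "A") -1 else 1
        ctr <- centers[i, ] + sgn * off * c(cos(ang), sin(ang))
        spec <- planted_aggregate(ctr, "disc", "nano", disc_diameter,
                                  n_locs,
                                  channel_fraction = if (side == "A") 1 else 0)
        loc_list[[length(loc_list) + 1L]] <-
          sample_aggregate(spec, params$jitter_sigma)
        labels <- c(labels, rep(paste0("pair", i, "_", side), n_locs))
      }
    }
    locs <- do.call(rbind, loc_list)
    locs$x <- pmin(pmax(locs$x, 0), extent[1])
    locs$y <- pmin(pmax(locs$y, 0), extent[2])
    locs$frame <- 0L
    list(fov = new_fov(locs, extent), truth = list(labels = labels))
  })
}
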