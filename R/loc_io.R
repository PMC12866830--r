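# Localization-table I/O and channel demultiplexing.
#
# The canonical internal unit is the micrometre: every threshold used
# downstream (Voronoi cell areas, background areas, class windows) is defined
# in um^2. Readers accept nm or um input with an explicit flag.

#' Default ONI-style column mapping for localization CSV exports
#'
#' Localization software exports vary in their header names; this mapping is
#' the configurable bridge. Names are the canonical fields, values the CSV
#' column names. `channel` and `precision` may be `NA` when the export lacks
#' them.
#'
#' @param x,y,frame,channel,precision CSV column names
#' @export
oni_column_map <- function(x = "X (nm)", y = "Y (nm)", frame = "Frame",
                           channel = NA_character_,
                           precision = NA_character_) {
  list(x = x, y = y, frame = frame, channel = channel, precision = precision)
}

#' Construct a field of view from a localization table
#'
#' @param locs data.frame with columns `x`, `y` (um), `frame`
#'   (non-negative integer), and optionally `channel`, `precision`
#' @param extent numeric length-2, FOV width and height in um
#' @param metadata named list (case/group/replicate labels, dye, ...)
#' @return object of class `fov`
#' @export
new_fov <- function(locs, extent, metadata = list()) {
  stopifnot(is.data.frame(locs), length(extent) == 2, all(extent > 0))
  for (col in c("channel", "precision")) {
    if (!col %in% names(locs)) locs[[col]] <- rep(NA, nrow(locs))
  }
  if (!"frame" %in% names(locs)) locs$frame <- rep(0L, nrow(locs))
  locs <- locs[, c("x", "y", "frame", "channel", "precision")]
  if (nrow(locs) > 0) {
    if (!all(is.finite(locs$x)) || !all(is.finite(locs$y)))
      stop("non-finite coordinates in localization table")
    if (any(locs$frame < 0)) stop("negative frame index")
    if (any(locs$x < 0 | locs$x > extent[1] | locs$y < 0 | locs$y > extent[2]))
      stop("localizations outside the declared field-of-view extent")
  }
  structure(list(locs = locs, extent = as.numeric(extent), metadata = metadata),
            class = "fov")
}

#' @export
print.fov <- function(x, ...) {
  cat(sprintf("<fov> %d localizations, %.3g x %.3g um\n",
              nrow(x$locs), x$extent[1], x$extent[2]))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a localization CSV into a field of view
#'
#' @param path CSV file path
#' @param column_map mapping from canonical fields to CSV columns, see
#'   [oni_column_map()]
#' @param unit unit of the coordinate columns, `"nm"` or `"um"`; converted to
#'   um internally
#' @param extent FOV extent in um; if `NULL`, taken as the ceiling of the
#'   coordinate range
#' @param metadata named list attached to the FOV
#' @return a [new_fov()] object; row order of the CSV is preserved
#' @export
read_localizations <- function(path, column_map = oni_column_map(),
                               unit = c("nm", "um"), extent = NULL,
                               metadata = list()) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("localization file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE)
  scale <- if (unit == "nm") 1e-3 else 1
  get_col <- function(field, required = TRUE) {
    cname <- column_map[[field]]
    if (is.null(cname) || is.na(cname)) {
      if (required) stop("no column mapped for required field '", field, "'")
      return(NULL)
    }
    if (!cname %in% names(raw)) {
      if (required) stop("missing column '", cname, "' (field '", field, "')")
      return(NULL)
    }
    raw[[cname]]
  }
  num_col <- function(v, field) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop("non-numeric value in field '", field, "' at row ", bad[1])
    out
  }
  x <- num_col(get_col("x"), "x") * scale
  y <- num_col(get_col("y"), "y") * scale
  frame <- get_col("frame", required = FALSE)
  frame <- if (is.null(frame)) rep(0L, length(x))
           else as.integer(num_col(frame, "frame"))
  channel <- get_col("channel", required = FALSE)
  precision <- get_col("precision", required = FALSE)
  precision <- if (is.null(precision)) NA_real_
               else num_col(precision, "precision") * scale
  locs <- data.frame(x = x, y = y, frame = frame,
                     channel = if (is.null(channel)) rep(NA, length(x))
                               else channel,
                     precision = if (length(precision) == 1 && length(x) != 1)
                                   rep(precision, length(x)) else precision)
  if (is.null(extent)) {
    extent <- if (nrow(locs) == 0) c(1, 1) else ceiling(c(max(x), max(y)))
    extent <- pmax(extent, 1)
  }
  new_fov(locs, extent, metadata)
}

#' Frame-block channel program for alternating-laser acquisitions
#'
#' Two-color acquisitions alternate excitation lasers in fixed frame blocks
#' (200 frames per block, 68000 frames total by default), so the channel of a
#' localization is recoverable from its frame index.
#'
#' @param block_length frames per laser block
#' @param channel_order ordered channel identifiers, cycled over blocks
#' @param total_frames total frames acquired; must be divisible by
#'   `block_length`
#' @export
channel_program <- function(block_length = 200, channel_order = c("A", "B"),
                            total_frames = 68000) {
  stopifnot(block_length > 0, length(channel_order) >= 1,
            total_frames %% block_length == 0)
  structure(list(block_length = as.integer(block_length),
                 channel_order = as.character(channel_order),
                 total_frames = as.integer(total_frames)),
            class = "channel_program")
}

#' Demultiplex an interleaved two-color acquisition by frame block
#'
#' Assigns each localization the channel of its frame block: block
#' `floor(frame / block_length)`, cycling through `channel_order`.
#'
#' @param fov a [new_fov()] object whose localizations have unset channel
#' @param program a [channel_program()]
#' @return the FOV with channels filled in
#' @export
demux_channels <- function(fov, program) {
  stopifnot(inherits(fov, "fov"), inherits(program, "channel_program"))
  if (any(!is.na(fov$locs$channel)))
    stop("localizations already carry a channel; demultiplexing would overwrite it")
  frame <- fov$locs$frame
  if (any(frame >= program$total_frames))
    stop("frame index ", max(frame), " >= total_frames (",
         program$total_frames, ")")
  block <- frame %/% program$block_length
  k <- length(program$channel_order)
  fov$locs$channel <- program$channel_order[(block %% k) + 1L]
  fov
}

#' Write an aggregate table to CSV
#'
#' One row per aggregate: id, per-channel localization counts, alpha-shape
#' area, size class and (when present) enrichment score and modification
#' category. Numeric fields round-trip losslessly through [read_aggregates()].
#'
#' @param aggregates list of aggregate objects (see [segment_fov()]) or a
#'   data.frame as produced by [aggregate_table()]
#' @param path output CSV path
#' @export
write_aggregates <- function(aggregates, path) {
  tab <- if (is.data.frame(aggregates)) aggregates else aggregate_table(aggregates)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an aggregate table written by [write_aggregates()]
#' @param path CSV path
#' @export
read_aggregates <- function(path) {
  if (!file.exists(path)) stop("aggregate table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  for (col in intersect(c("n_locs", "n_A", "n_B"), names(tab)))
    tab[[col]] <- as.integer(tab[[col]])
  tab
}

#' Read a declarative run configuration (YAML)
#'
#' Thresholds, dye label, extent and seeds for a pipeline run live in one
#' config file; values omitted there fall back to package defaults.
#' @param path YAML file path
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
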