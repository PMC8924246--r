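#' Localisation tables
#'
#' The substrate of all spatial statistics: one row per detected molecule
#' with 2D coordinates in nm, the acquisition frame, the fitted localisation
#' precision (nm) and a channel label. The canonical on-disk dialect is a
#' comma-delimited file with header `x_nm, y_nm, frame, precision_nm,
#' channel`; adapters map vendor exports (ThunderSTORM, Zeiss Zen) onto it.
#'
#' @name loc_table
NULL

# column maps: canonical name -> candidate source column names
.loc_dialects <- list(
  canonical    = c(x = "x_nm", y = "y_nm", frame = "frame",
                   precision = "precision_nm", channel = "channel"),
  thunderstorm = c(x = "x [nm]", y = "y [nm]", frame = "frame",
                   precision = "uncertainty [nm]", channel = "channel"),
  zeiss        = c(x = "Position X [nm]", y = "Position Y [nm]",
                   frame = "First Frame", precision = "Precision [nm]",
                   channel = "Channel")
)

new_loc_table <- function(x, y, frame, precision, channel, report = NULL) {
  d <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  frame = as.integer(frame),
                  precision = as.numeric(precision),
                  channel = as.character(channel),
                  stringsAsFactors = FALSE)
  structure(d, class = c("loc_table", "data.frame"),
            report = report %||% list(kept = nrow(d), dropped = 0L))
}

#' Construct a localisation table from vectors
#'
#' @param x,y coordinates (nm).
#' @param frame integer frame index (default 1).
#' @param precision localisation precision (nm), must be positive
#'   (default 20 nm, typical for Alexa-Fluor 647).
#' @param channel channel label (default `"ch1"`).
#' @return a `loc_table` (data.frame subclass).
#' @examples
#' loc_table(c(0, 10), c(0, 5))
#' @export
loc_table <- function(x, y, frame = 1L, precision = 20, channel = "ch1") {
  n <- length(x)
  new_loc_table(x, y, rep_len(frame, n), rep_len(precision, n),
                rep_len(channel, n))
}

#' @export
print.loc_table <- function(x, ...) {
  rep <- attr(x, "report")
  cat(sprintf("Localisation table: %d molecules, %d channel(s)",
              nrow(x), length(unique(x$channel))))
  if (nrow(x) > 0)
    cat(sprintf(", mean precision %.1f nm", mean(x$precision)))
  cat("\n")
  if (!is.null(rep) && rep$dropped > 0)
    cat(sprintf("  (%d rows dropped by validation/clipping)\n", rep$dropped))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

validate_loc_rows <- function(d) {
  ok <- is.finite(d$x) & is.finite(d$y) &
    is.finite(d$precision) & d$precision > 0 &
    !is.na(d$frame) &
    !is.na(d$channel) & nzchar(d$channel)
  ok
}

#' Read a localisation table from delimited text
#'
#' Rows failing validation (non-finite coordinates, precision <= 0, empty
#' channel) are dropped and counted in the attached report.
#'
#' @param path CSV file path.
#' @param dialect `"canonical"`, `"thunderstorm"`, `"zeiss"`, or a named
#'   character vector mapping `x`, `y`, `frame`, `precision`, `channel` to
#'   source column names.
#' @param default_channel label used when the file has no channel column.
#' @return a `loc_table`; `attr(, "report")` holds kept/dropped counts.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(x_nm = c(1, 2), y_nm = c(3, 4), frame = 1,
#'                      precision_nm = 20, channel = "a"), f, row.names = FALSE)
#' read_localizations(f)
#' @export
read_localizations <- function(path, dialect = "canonical",
                               default_channel = "ch1") {
  if (!file.exists(path))
    stopf("localisation file not found: %s", path, class = "nucleopol_io_error")
  map <- if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(.loc_dialects))
      stopf("unknown dialect '%s'", dialect, class = "nucleopol_format_error")
    .loc_dialects[[dialect]]
  } else dialect
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("x", "y", "frame", "precision")
  miss <- need[!map[need] %in% names(raw)]
  if (length(miss))
    stopf("missing required column(s): %s",
          paste(map[miss], collapse = ", "), class = "nucleopol_format_error")
  ch <- if (map[["channel"]] %in% names(raw)) raw[[map[["channel"]]]]
        else default_channel
  d <- data.frame(x = as.numeric(raw[[map[["x"]]]]),
                  y = as.numeric(raw[[map[["y"]]]]),
                  frame = suppressWarnings(as.integer(raw[[map[["frame"]]]])),
                  precision = as.numeric(raw[[map[["precision"]]]]),
                  channel = as.character(rep_len(ch, nrow(raw))),
                  stringsAsFactors = FALSE)
  ok <- validate_loc_rows(d)
  if (!any(ok))
    stopf("no valid localisations in %s", path, class = "nucleopol_empty_error")
  new_loc_table(d$x[ok], d$y[ok], d$frame[ok], d$precision[ok], d$channel[ok],
                report = list(kept = sum(ok), dropped = sum(!ok)))
}

#' Write a localisation table in the canonical dialect
#'
#' @param locs a `loc_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  stopifnot(inherits(locs, "loc_table"))
  out <- data.frame(x_nm = locs$x, y_nm = locs$y, frame = locs$frame,
                    precision_nm = locs$precision, channel = locs$channel)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clip a localisation table to an ROI
#'
#' Keeps rows whose (x, y) falls inside the polygon; boundary points
#' (including vertices) are retained. Idempotent.
#'
#' @param locs a `loc_table`.
#' @param roi an [roi_polygon()] object.
#' @return the clipped `loc_table`.
#' @export
clip_to_roi <- function(locs, roi) {
  stopifnot(inherits(locs, "loc_table"))
  if (!inherits(roi, "roi"))
    stopf("roi must be an roi object", class = "nucleopol_geometry_error")
  keep <- points_in_roi(locs$x, locs$y, roi)
  out <- locs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(kept = sum(keep), dropped = sum(!keep))
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Trajectory tables
#'
#' 3D (or 2D) single-particle tracks: `track_id`, `frame`, `t` (s) and
#' coordinates in um. Frames must be strictly increasing within a track;
#' non-uniform frame intervals are flagged as gaps. Tracks shorter than the
#' minimum frame count (default 10, the standard tracking cut-off) are
#' excluded.
#'
#' @name trajectory_set
NULL

.traj_dialects <- list(
  canonical = c(track_id = "track_id", frame = "frame", t = "t",
                x = "x_um", y = "y_um", z = "z_um"),
  mosaic    = c(track_id = "Trajectory", frame = "Frame", t = "t",
                x = "x", y = "y", z = "z")
)

new_trajectory_set <- function(d, dt, excluded = 0L, gap_tracks = integer(0)) {
  structure(d, class = c("trajectory_set", "data.frame"),
            dt = dt, excluded = excluded, gap_tracks = gap_tracks)
}

#' Construct a trajectory set from a data frame
#'
#' @param d data.frame with `track_id`, `frame`, `x`, `y` and optionally
#'   `z` (um) and `t` (s).
#' @param min_frames minimum frames per track; shorter tracks are dropped
#'   and counted (default 10).
#' @param dt frame interval in seconds used when `t` is absent
#'   (default 0.032 s).
#' @return a `trajectory_set` (data.frame subclass) with attributes `dt`,
#'   `excluded` (tracks dropped for length) and `gap_tracks`.
#' @export
trajectory_set <- function(d, min_frames = 10, dt = 0.032) {
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(d)))
    stopf("trajectory data needs columns %s", paste(need, collapse = ", "),
          class = "nucleopol_format_error")
  d <- d[order(d$track_id, d$frame), , drop = FALSE]
  if (!"z" %in% names(d)) d$z <- NA_real_
  if (!"t" %in% names(d)) d$t <- d$frame * dt
  d$track_id <- as.integer(d$track_id)
  d$frame <- as.integer(d$frame)
  by_track <- split(seq_len(nrow(d)), d$track_id)
  gap_tracks <- integer(0)
  for (id in names(by_track)) {
    f <- d$frame[by_track[[id]]]
    df <- diff(f)
    if (any(df <= 0))
      stopf("non-monotonic frames in track %s", id,
            class = "nucleopol_format_error")
    if (length(df) && any(df != df[1]))
      gap_tracks <- c(gap_tracks, as.integer(id))
  }
  len <- lengths(by_track)
  keep_ids <- as.integer(names(by_track))[len >= min_frames]
  excluded <- sum(len < min_frames)
  out <- d[d$track_id %in% keep_ids,
           c("track_id", "frame", "t", "x", "y", "z"), drop = FALSE]
  rownames(out) <- NULL
  new_trajectory_set(out, dt, as.integer(excluded),
                     intersect(gap_tracks, keep_ids))
}

#' Read a trajectory table from delimited text
#'
#' @inheritParams trajectory_set
#' @param path CSV file path.
#' @param dialect `"canonical"`, `"mosaic"`, or a named map like in
#'   [read_localizations()].
#' @return a `trajectory_set`.
#' @export
read_trajectories <- function(path, dialect = "canonical", min_frames = 10,
                              dt = 0.032) {
  if (!file.exists(path))
    stopf("trajectory file not found: %s", path, class = "nucleopol_io_error")
  map <- if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(.traj_dialects))
      stopf("unknown dialect '%s'", dialect, class = "nucleopol_format_error")
    .traj_dialects[[dialect]]
  } else dialect
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  miss <- need[!map[need] %in% names(raw)]
  if (length(miss))
    stopf("missing required column(s): %s",
          paste(map[miss], collapse = ", "), class = "nucleopol_format_error")
  d <- data.frame(track_id = raw[[map[["track_id"]]]],
                  frame = raw[[map[["frame"]]]],
                  x = as.numeric(raw[[map[["x"]]]]),
                  y = as.numeric(raw[[map[["y"]]]]))
  if (map[["z"]] %in% names(raw)) d$z <- as.numeric(raw[[map[["z"]]]])
  if (map[["t"]] %in% names(raw)) d$t <- as.numeric(raw[[map[["t"]]]])
  trajectory_set(d, min_frames = min_frames, dt = dt)
}

#' Write a trajectory set in the canonical dialect
#'
#' @param traj a `trajectory_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  out <- data.frame(track_id = traj$track_id, frame = traj$frame, t = traj$t,
                    x_um = traj$x, y_um = traj$y, z_um = traj$z)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d tracks, %d positions (dt = %g s)\n",
              length(unique(x$track_id)), nrow(x), attr(x, "dt")))
  if (attr(x, "excluded") > 0)
    cat(sprintf("  (%d short tracks excluded)\n", attr(x, "excluded")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
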