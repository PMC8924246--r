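#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking with the standard
#' constraints: no link longer than `max_disp` (400 nm = 0.4 um by
#' default) and tracks shorter than `min_frames` (10) discarded. Within a
#' frame transition, candidate links are assigned in ascending distance
#' order; unmatched detections seed new tracks.
#'
#' @param detections data.frame with `frame`, `x`, `y` and optionally `z`
#'   (um).
#' @param max_disp maximum frame-to-frame displacement (um).
#' @param min_frames minimum track length in frames.
#' @param dt frame interval (s).
#' @return a `trajectory_set`.
#' @export
link_tracks <- function(detections, max_disp = 0.4, min_frames = 10,
                        dt = 0.032) {
  stopifnot(max_disp > 0)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(detections)))
    stopf("detections need columns %s", paste(need, collapse = ", "),
          class = "nucleopol_format_error")
  d <- detections[order(detections$frame), , drop = FALSE]
  if (!"z" %in% names(d)) d$z <- 0
  frames <- sort(unique(d$frame))
  track_of <- integer(nrow(d))       # row -> track id
  next_id <- 0L
  # active track ends: row indices into d, per track
  prev_rows <- which(d$frame == frames[1])
  track_of[prev_rows] <- seq_along(prev_rows)
  next_id <- length(prev_rows)
  for (fi in seq_along(frames)[-1]) {
    cur_rows <- which(d$frame == frames[fi])
    linked_cur <- rep(FALSE, length(cur_rows))
    if (frames[fi] - frames[fi - 1] == 1 && length(prev_rows)) {
      dx <- outer(d$x[prev_rows], d$x[cur_rows], "-")
      dy <- outer(d$y[prev_rows], d$y[cur_rows], "-")
      dz <- outer(d$z[prev_rows], d$z[cur_rows], "-")
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      cand <- which(dist <= max_disp, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(dist[cand])
        used_p <- rep(FALSE, length(prev_rows))
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (used_p[i] || linked_cur[j]) next
          used_p[i] <- TRUE; linked_cur[j] <- TRUE
          track_of[cur_rows[j]] <- track_of[prev_rows[i]]
        }
      }
    }
    new_rows <- cur_rows[!linked_cur]
    if (length(new_rows)) {
      track_of[new_rows] <- next_id + seq_along(new_rows)
      next_id <- next_id + length(new_rows)
    }
    prev_rows <- cur_rows
  }
  out <- data.frame(track_id = track_of, frame = d$frame,
                    x = d$x, y = d$y, z = d$z)
  trajectory_set(out, min_frames = min_frames, dt = dt)
}

#' Time-averaged mean squared displacement of one track
#'
#' `msd(tau_k) = mean over t of ||r(t + tau_k) - r(t)||^2` using all
#' overlapping position pairs at each lag; pairs spanning missing frames
#' are excluded.
#'
#' @param track data.frame with `frame`, `t`, `x`, `y` and optionally `z`
#'   (um); one track.
#' @param max_lag largest lag in frames (default all available).
#' @return a data.frame of class `msd_curve` with columns `lag` (frames),
#'   `tau` (s), `msd` (um^2), `n_pairs`.
#' @examples
#' tr <- data.frame(frame = 1:3, t = (1:3) * 0.032,
#'                  x = c(0, 1, 2), y = 0, z = 0)
#' compute_msd(tr)
#' @export
compute_msd <- function(track, max_lag = NULL) {
  f <- track$frame
  if (is.unsorted(f, strictly = TRUE))
    stopf("track frames must be strictly increasing",
          class = "nucleopol_format_error")
  use_z <- "z" %in% names(track) && !all(is.na(track$z))
  dt <- if ("t" %in% names(track) && nrow(track) > 1)
    min(diff(track$t) / diff(f)) else 0.032
  span <- max(f) - min(f)
  max_lag <- min(max_lag %||% span, span)
  idx <- match(seq(min(f), max(f)), f)   # frame -> row (NA for gaps)
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  n_pairs <- integer(max_lag)
  nf <- length(idx)
  for (k in lags) {
    i0 <- idx[seq_len(nf - k)]
    i1 <- idx[seq_len(nf - k) + k]
    ok <- !is.na(i0) & !is.na(i1)
    n_pairs[k] <- sum(ok)
    if (!n_pairs[k]) { msd[k] <- NA_real_; next }
    sq <- (track$x[i1[ok]] - track$x[i0[ok]])^2 +
      (track$y[i1[ok]] - track$y[i0[ok]])^2
    if (use_z) sq <- sq + (track$z[i1[ok]] - track$z[i0[ok]])^2
    msd[k] <- mean(sq)
  }
  structure(data.frame(lag = lags, tau = lags * dt, msd = msd,
                       n_pairs = n_pairs),
            class = c("msd_curve", "data.frame"),
            dims = if (use_z) 3L else 2L)
}

#' Mobility class from a diffusion coefficient
#'
#' Static: D < 0.1 um^2 s^-1; diffusive: 0.1 <= D <= 5; hypermobile:
#' D > 5. The class is a pure function of D; boundary values fall in the
#' diffusive class.
#'
#' @param D diffusion coefficient(s), um^2 s^-1.
#' @return character vector.
#' @export
classify_mobility <- function(D) {
  out <- rep(NA_character_, length(D))
  out[!is.na(D) & D < 0.1] <- "static"
  out[!is.na(D) & D >= 0.1 & D <= 5] <- "diffusive"
  out[!is.na(D) & D > 5] <- "hypermobile"
  out
}

#' Fit an anomalous diffusion model to an MSD curve
#'
#' Linear least squares on `log msd = log(2 dims D) + alpha log tau` over
#' the first `fit_lags` lags with positive MSD. By default the first 25%
#' of available lags are used (at least 3, at most 10), the standard
#' bias/variance compromise for time-averaged MSD. An all-zero curve
#' returns D = 0, class static, `alpha` NA; fewer than 3 positive lags
#' sets the `fit_failed` flag.
#'
#' @param curve a [compute_msd()] result.
#' @param dims spatial dimensionality (2 or 3); defaults to the curve's.
#' @param fit_lags number of lags to fit, or `NULL` for the default rule.
#' @return a list of class `msd_fit`: `D` (um^2 s^-1), `alpha`, `dims`,
#'   `fit_lags`, `rss` (um^4, on the linear scale), `mobility_class`,
#'   `fit_failed`.
#' @examples
#' tau <- (1:20) * 0.032
#' curve <- structure(data.frame(lag = 1:20, tau = tau,
#'                               msd = 6 * 0.4 * tau, n_pairs = 20),
#'                    class = c("msd_curve", "data.frame"), dims = 3L)
#' fit_anomalous(curve)  # recovers D = 0.4, alpha = 1
#' @export
fit_anomalous <- function(curve, dims = NULL, fit_lags = NULL) {
  dims <- dims %||% attr(curve, "dims") %||% 3L
  ok <- !is.na(curve$msd)
  if (all(curve$msd[ok] == 0)) {
    return(structure(list(D = 0, alpha = NA_real_, dims = dims,
                          fit_lags = 0L, rss = 0,
                          mobility_class = "static", fit_failed = FALSE),
                     class = "msd_fit"))
  }
  n_avail <- sum(ok)
  n_fit <- fit_lags %||% max(3L, min(10L, ceiling(0.25 * n_avail)))
  usable <- which(ok & curve$msd > 0)
  usable <- usable[seq_len(min(n_fit, length(usable)))]
  if (length(usable) < 3) {
    return(structure(list(D = NA_real_, alpha = NA_real_, dims = dims,
                          fit_lags = length(usable), rss = NA_real_,
                          mobility_class = NA_character_,
                          fit_failed = TRUE),
                     class = "msd_fit"))
  }
  lt <- log(curve$tau[usable]); lm_ <- log(curve$msd[usable])
  fit <- lm(lm_ ~ lt)
  alpha <- unname(coef(fit)[2])
  D <- exp(unname(coef(fit)[1])) / (2 * dims)
  pred <- exp(unname(coef(fit)[1])) * curve$tau[usable]^alpha
  structure(list(D = D, alpha = alpha, dims = dims,
                 fit_lags = length(usable),
                 rss = sum((curve$msd[usable] - pred)^2),
                 mobility_class = classify_mobility(D),
                 fit_failed = FALSE),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  if (x$fit_failed) cat("MSD fit: failed (too few positive lags)\n")
  else cat(sprintf("MSD fit: D = %.3g um^2/s, alpha = %.3g (%s, %d lags)\n",
                   x$D, x$alpha, x$mobility_class, x$fit_lags))
  invisible(x)
}

#' Fit every track in a trajectory set
#'
#' @param traj a `trajectory_set`.
#' @param dims 2 or 3; default 3 when z is present.
#' @param fit_lags passed to [fit_anomalous()].
#' @return data.frame with one row per track: `track_id`, `D`, `alpha`,
#'   `class`, `rss`, `fit_lags`, `fit_failed`.
#' @export
fit_tracks <- function(traj, dims = NULL, fit_lags = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  ids <- unique(traj$track_id)
  rows <- lapply(ids, function(id) {
    tr <- traj[traj$track_id == id, , drop = FALSE]
    fit <- fit_anomalous(compute_msd(tr), dims = dims, fit_lags = fit_lags)
    data.frame(track_id = id, D = fit$D, alpha = fit$alpha,
               class = fit$mobility_class, rss = fit$rss,
               fit_lags = fit$fit_lags, fit_failed = fit$fit_failed)
  })
  do.call(rbind, rows)
}

#' Per-cell mobility summary
#'
#' `static_fraction` is the share of classified tracks in the static
#' class; `mean_D` averages the static and diffusive classes only
#' (hypermobile tracks, not quantified in the source analysis, are
#' excluded unless `include_hypermobile`).
#'
#' @param fits a [fit_tracks()] data.frame.
#' @param include_hypermobile include hypermobile tracks in `mean_D`.
#' @return a list of class `mobility_summary`: `mean_D`,
#'   `static_fraction`, `mobile_fraction`, `n_tracks`; `empty` flags zero
#'   successful fits.
#' @export
summarize_mobility <- function(fits, include_hypermobile = FALSE) {
  ok <- !fits$fit_failed & !is.na(fits$class)
  if (!any(ok))
    return(structure(list(mean_D = NA_real_, static_fraction = NA_real_,
                          mobile_fraction = NA_real_, n_tracks = 0L,
                          empty = TRUE),
                     class = "mobility_summary"))
  cl <- fits$class[ok]
  stat <- mean(cl == "static")
  keep_d <- if (include_hypermobile) ok else ok & fits$class != "hypermobile"
  structure(list(mean_D = mean(fits$D[keep_d]),
                 static_fraction = stat,
                 mobile_fraction = 1 - stat,
                 n_tracks = sum(ok), empty = FALSE),
            class = "mobility_summary")
}

#' @export
print.mobility_summary <- function(x, ...) {
  if (x$empty) { cat("Mobility summary: no successful fits\n"); return(invisible(x)) }
  cat(sprintf(paste0("Mobility summary: %d tracks, mean D = %.3g um^2/s, ",
                     "%.0f%% static / %.0f%% mobile\n"),
              x$n_tracks, x$mean_D, 100 * x$static_fraction,
              100 * x$mobile_fraction))
  invisible(x)
}
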