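#' Simulate complete spatial randomness (CSR)
#'
#' Uniform points over the ROI; the null model under which the linearised
#' Ripley curve L(r) - r is zero at all radii.
#'
#' @param n number of points.
#' @param roi an [roi_polygon()]; default a 10 x 10 um square, the scale of
#'   a HeLa nucleus mid-section.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param precision reported localisation precision (nm) for the table.
#' @param channel channel label.
#' @return a `loc_table`.
#' @examples
#' simulate_csr(100, seed = 1)
#' @export
simulate_csr <- function(n, roi = roi_rect(10000, 10000), seed = 1,
                         precision = 20, channel = "ch1") {
  stopifnot(n >= 0)
  if (n == 0) return(loc_table(numeric(0), numeric(0)))
  p <- with_seed(stream_seed(seed, "csr"), runif_in_roi(n, roi))
  loc_table(p$x, p$y, frame = seq_len(n), precision = precision,
            channel = channel)
}

#' Specification of a clustered (Thomas-process) point pattern
#'
#' Defaults reproduce the measured nuclear myosin VI regime: ~504 clusters
#' per nucleus of ~64 molecules each, with 81% of molecules in clusters
#' (background fraction 0.19), in a 10 x 10 um ROI. `cluster_sigma` is the
#' Gaussian scatter of molecules about their cluster centre; 15 nm gives
#' compact clusters of roughly the reported ~1200 nm^2 mean area.
#' `precision_sigma` adds localisation jitter on top (20 nm, the typical
#' Alexa-Fluor 647 precision).
#'
#' @param roi an [roi_polygon()].
#' @param n_clusters number of cluster centres.
#' @param molecules_per_cluster mean molecules per cluster (Poisson).
#' @param cluster_sigma Gaussian cluster scatter sd (nm).
#' @param background_fraction fraction of all molecules that are uniform
#'   background, in [0, 1).
#' @param precision_sigma localisation jitter sd (nm).
#' @param seed integer seed.
#' @return a list of class `pattern_spec`.
#' @export
pattern_spec <- function(roi = roi_rect(10000, 10000), n_clusters = 504,
                         molecules_per_cluster = 64, cluster_sigma = 15,
                         background_fraction = 0.19, precision_sigma = 20,
                         seed = 1) {
  if (n_clusters < 0 || molecules_per_cluster < 1 || cluster_sigma <= 0 ||
      background_fraction < 0 || background_fraction >= 1 ||
      precision_sigma < 0)
    stopf("invalid pattern specification", class = "nucleopol_parameter_error")
  structure(list(roi = roi, n_clusters = n_clusters,
                 molecules_per_cluster = molecules_per_cluster,
                 cluster_sigma = cluster_sigma,
                 background_fraction = background_fraction,
                 precision_sigma = precision_sigma, seed = seed),
            class = "pattern_spec")
}

#' Simulate a clustered localisation pattern (Thomas process)
#'
#' Cluster centres are uniform in the ROI; per-cluster molecule counts are
#' Poisson around the mean; member offsets are isotropic Gaussian with sd
#' `cluster_sigma`; uniform background points make up `background_fraction`
#' of the total; Gaussian localisation jitter (sd `precision_sigma`) is
#' added to every point. Ground truth (cluster centres and per-point labels,
#' 0 = background) is attached as `attr(, "truth")` and is never read by
#' any analysis function.
#'
#' @param spec a [pattern_spec()].
#' @param channel channel label for the output table.
#' @return a `loc_table` with a `truth` attribute
#'   (`list(centers, labels, spec)`).
#' @examples
#' p <- simulate_clustered(pattern_spec(n_clusters = 20, seed = 7))
#' table(attr(p, "truth")$labels == 0)  # background vs clustered
#' @export
simulate_clustered <- function(spec = pattern_spec(), channel = "ch1") {
  stopifnot(inherits(spec, "pattern_spec"))
  roi <- spec$roi
  centers <- with_seed(stream_seed(spec$seed, "centers"),
                       runif_in_roi(spec$n_clusters, roi))
  counts <- with_seed(stream_seed(spec$seed, "counts"),
                      rpois(spec$n_clusters, spec$molecules_per_cluster))
  n_clustered <- sum(counts)
  lab <- rep(seq_len(spec$n_clusters), counts)
  off <- with_seed(stream_seed(spec$seed, "offsets"),
                   list(x = rnorm(n_clustered, 0, spec$cluster_sigma),
                        y = rnorm(n_clustered, 0, spec$cluster_sigma)))
  x <- rep(centers$x, counts) + off$x
  y <- rep(centers$y, counts) + off$y
  bf <- spec$background_fraction
  n_bg <- if (bf > 0) round(n_clustered * bf / (1 - bf)) else 0L
  if (n_bg > 0) {
    bg <- with_seed(stream_seed(spec$seed, "background"),
                    runif_in_roi(n_bg, roi))
    x <- c(x, bg$x); y <- c(y, bg$y)
    lab <- c(lab, rep(0L, n_bg))
  }
  n <- length(x)
  if (spec$precision_sigma > 0) {
    jit <- with_seed(stream_seed(spec$seed, "jitter"),
                     list(x = rnorm(n, 0, spec$precision_sigma),
                          y = rnorm(n, 0, spec$precision_sigma)))
    x <- x + jit$x; y <- y + jit$y
  }
  prec <- with_seed(stream_seed(spec$seed, "precision"),
                    pmax(1, rnorm(n, max(spec$precision_sigma, 1),
                                  0.1 * max(spec$precision_sigma, 1))))
  out <- loc_table(x, y, frame = seq_len(n), precision = prec,
                   channel = channel)
  attr(out, "truth") <- list(centers = data.frame(x = centers$x,
                                                  y = centers$y),
                             labels = as.integer(lab), spec = spec)
  out
}

#' Specification of a two-channel colocalised pattern
#'
#' A `coloc_fraction` share of channel-B cluster centres is placed at
#' channel-A cluster centres displaced by Gaussian noise; the remaining B
#' clusters are independent. The measured regime (15% of myosin VI and 22%
#' of RNAPII molecules colocalised at DoC threshold 0.4) corresponds to a
#' modest shared-centre share; the default 0.2 sits in that range.
#'
#' @param spec_a,spec_b [pattern_spec()]s for the two channels.
#' @param coloc_fraction share of B cluster centres placed at A centres,
#'   in [0, 1].
#' @param displacement_sigma sd (nm) of the Gaussian displacement applied
#'   to shared centres.
#' @param seed integer seed.
#' @return a list of class `two_channel_spec`.
#' @export
two_channel_spec <- function(spec_a = pattern_spec(),
                             spec_b = pattern_spec(),
                             coloc_fraction = 0.2,
                             displacement_sigma = 20, seed = 1) {
  if (coloc_fraction < 0 || coloc_fraction > 1 || displacement_sigma < 0)
    stopf("invalid two-channel specification",
          class = "nucleopol_parameter_error")
  structure(list(spec_a = spec_a, spec_b = spec_b,
                 coloc_fraction = coloc_fraction,
                 displacement_sigma = displacement_sigma, seed = seed),
            class = "two_channel_spec")
}

#' Simulate a two-channel colocalised pattern
#'
#' @param spec a [two_channel_spec()].
#' @return `list(a, b)` of `loc_table`s (channels `"A"`, `"B"`). The B
#'   table's truth records which B clusters share an A centre
#'   (`shared`, logical) and the realised shared share.
#' @export
simulate_two_channel <- function(spec = two_channel_spec()) {
  stopifnot(inherits(spec, "two_channel_spec"))
  sa <- spec$spec_a
  sa$seed <- stream_seed(spec$seed, "channelA")
  a <- simulate_clustered(sa, channel = "A")
  centers_a <- attr(a, "truth")$centers

  sb <- spec$spec_b
  n_b <- sb$n_clusters
  n_shared <- round(spec$coloc_fraction * n_b)
  # B centres: first n_shared at (displaced) A centres, rest independent
  sb_ind <- sb
  sb_ind$seed <- stream_seed(spec$seed, "channelB")
  b_ind <- simulate_clustered(sb_ind, channel = "B")  # template, re-centred below
  centers_b <- attr(b_ind, "truth")$centers
  shared <- rep(FALSE, n_b)
  if (n_shared > 0) {
    pick <- with_seed(stream_seed(spec$seed, "pick"),
                      sample.int(nrow(centers_a), n_shared,
                                 replace = n_shared > nrow(centers_a)))
    disp <- with_seed(stream_seed(spec$seed, "displacement"),
                      list(x = rnorm(n_shared, 0, spec$displacement_sigma),
                           y = rnorm(n_shared, 0, spec$displacement_sigma)))
    new_cx <- centers_a$x[pick] + disp$x
    new_cy <- centers_a$y[pick] + disp$y
    lab <- attr(b_ind, "truth")$labels
    for (k in seq_len(n_shared)) {
      sel <- lab == k
      b_ind$x[sel] <- b_ind$x[sel] - centers_b$x[k] + new_cx[k]
      b_ind$y[sel] <- b_ind$y[sel] - centers_b$y[k] + new_cy[k]
    }
    centers_b$x[seq_len(n_shared)] <- new_cx
    centers_b$y[seq_len(n_shared)] <- new_cy
    shared[seq_len(n_shared)] <- TRUE
  }
  truth_b <- attr(b_ind, "truth")
  truth_b$centers <- centers_b
  truth_b$shared <- shared
  truth_b$shared_share <- n_shared / n_b
  attr(b_ind, "truth") <- truth_b
  list(a = a, b = b_ind)
}

#' Specification of simulated single-particle tracks
#'
#' Trajectories are fractional Brownian motion with Hurst exponent
#' `alpha / 2`, scaled so the ensemble MSD obeys
#' `MSD(tau) = 2 * dims * D * tau^alpha`; `alpha = 1` reduces to ordinary
#' Brownian motion with independent Gaussian steps. Defaults emulate the
#' live-cell acMFM regime: 3D tracks at 32 ms frame interval with 20 nm
#' localisation error, D around the reported nuclear means
#' (0.4 um^2 s^-1).
#'
#' @param n_tracks number of tracks.
#' @param frames frames per track.
#' @param dt frame interval (s).
#' @param D diffusion coefficient (um^2 s^-1).
#' @param alpha anomalous exponent (> 0).
#' @param dims 2 or 3.
#' @param loc_error_sigma localisation error sd per axis (um).
#' @param mixture optional list of components
#'   `list(weight =, D =, alpha =)`; weights must sum to 1. Overrides
#'   `D`/`alpha`; track counts per component are deterministic
#'   (`round(weight * n_tracks)`).
#' @param seed integer seed.
#' @return a list of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_tracks = 200, frames = 100, dt = 0.032,
                           D = 0.4, alpha = 1, dims = 3,
                           loc_error_sigma = 0.02, mixture = NULL,
                           seed = 1) {
  if (n_tracks < 1 || frames < 2 || dt <= 0 || D < 0 || alpha <= 0 ||
      !dims %in% c(2, 3) || loc_error_sigma < 0)
    stopf("invalid track simulation spec", class = "nucleopol_parameter_error")
  if (!is.null(mixture)) {
    w <- vapply(mixture, function(m) m$weight, numeric(1))
    if (abs(sum(w) - 1) > 1e-8)
      stopf("mixture weights must sum to 1", class = "nucleopol_parameter_error")
    for (m in mixture)
      if (m$D < 0 || (m$alpha %||% 1) <= 0)
        stopf("invalid mixture component", class = "nucleopol_parameter_error")
  }
  structure(list(n_tracks = n_tracks, frames = frames, dt = dt, D = D,
                 alpha = alpha, dims = dims,
                 loc_error_sigma = loc_error_sigma, mixture = mixture,
                 seed = seed),
            class = "track_sim_spec")
}

# Cholesky factor of the fractional Gaussian noise covariance for one axis:
# increments over dt with Var(disp over k steps) = 2 D (k dt)^alpha
fgn_chol <- function(m, dt, D, alpha) {
  if (D == 0) return(matrix(0, m, m))
  g <- function(k) D * dt^alpha * (abs(k + 1)^alpha - 2 * abs(k)^alpha +
                                     abs(k - 1)^alpha)
  k <- outer(seq_len(m), seq_len(m), function(i, j) abs(i - j))
  S <- matrix(g(k), m, m)
  # tiny ridge keeps the factorisation stable for alpha near 2
  chol(S + diag(1e-12 * max(diag(S)), m))
}

#' Simulate single-particle trajectories
#'
#' @param spec a [track_sim_spec()].
#' @return a `trajectory_set`; `attr(, "truth")` is a data.frame with the
#'   generating `D`, `alpha` and mobility class per track.
#' @examples
#' tr <- simulate_tracks(track_sim_spec(n_tracks = 5, frames = 20, seed = 3))
#' head(attr(tr, "truth"))
#' @export
simulate_tracks <- function(spec = track_sim_spec()) {
  stopifnot(inherits(spec, "track_sim_spec"))
  comps <- spec$mixture %||%
    list(list(weight = 1, D = spec$D, alpha = spec$alpha))
  n_per <- vapply(comps, function(m) m$weight * spec$n_tracks, numeric(1))
  n_per <- round(n_per)
  n_per[length(n_per)] <- spec$n_tracks - sum(n_per[-length(n_per)])
  m <- spec$frames - 1L
  frames <- seq_len(spec$frames)
  rows <- vector("list", length(comps))
  truth <- vector("list", length(comps))
  id0 <- 0L
  for (ci in seq_along(comps)) {
    cm <- comps[[ci]]
    nk <- n_per[ci]
    if (nk == 0) next
    alpha_c <- cm$alpha %||% 1
    L <- fgn_chol(m, spec$dt, cm$D, alpha_c)
    seed_c <- stream_seed(spec$seed, paste0("tracks", ci))
    coords <- with_seed(seed_c, {
      lapply(seq_len(spec$dims), function(ax) {
        z <- matrix(rnorm(m * nk), m, nk)
        steps <- crossprod(L, z)            # m x nk increments per axis
        pos <- rbind(0, apply(steps, 2, cumsum))
        if (spec$loc_error_sigma > 0)
          pos <- pos + matrix(rnorm(spec$frames * nk, 0,
                                    spec$loc_error_sigma),
                              spec$frames, nk)
        pos
      })
    })
    ids <- id0 + seq_len(nk)
    rows[[ci]] <- data.frame(
      track_id = rep(ids, each = spec$frames),
      frame = rep(frames, nk),
      x = as.vector(coords[[1]]),
      y = as.vector(coords[[2]]),
      z = if (spec$dims == 3) as.vector(coords[[3]]) else NA_real_)
    truth[[ci]] <- data.frame(track_id = ids, D = cm$D, alpha = alpha_c,
                              class = classify_mobility(cm$D))
    id0 <- id0 + nk
  }
  d <- do.call(rbind, rows)
  out <- trajectory_set(d, min_frames = 2, dt = spec$dt)
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "dims") <- spec$dims
  out
}

#' Specification of a simulated ATPase titration
#'
#' Steady-state actin-activated ATPase rates follow a Michaelis-Menten
#' curve with basal offset: `rate = V0 + kcat * A / (K_actin + A)`.
#' Defaults use the wild-type myosin VI kcat of 5.5 s^-1; the paper-style
#' titration spans 0-30 uM actin. V0 and K_actin are not reported for this
#' system, so typical myosin VI values are used (V0 = 0.04 s^-1,
#' K_actin = 3 uM).
#'
#' @param actin_concs actin concentrations (uM).
#' @param V0 basal ATPase rate (s^-1).
#' @param kcat maximal actin-activated rate (s^-1).
#' @param K_actin actin concentration at half-maximal activation (uM).
#' @param noise_sd Gaussian measurement noise sd (s^-1).
#' @param seed integer seed.
#' @return a list of class `kinetics_sim_spec`.
#' @export
kinetics_sim_spec <- function(actin_concs = c(0, 1.25, 2.5, 5, 10, 15, 20, 30),
                              V0 = 0.04, kcat = 5.5, K_actin = 3,
                              noise_sd = 0.15, seed = 1) {
  if (any(actin_concs < 0) || kcat <= 0 || K_actin <= 0 || V0 < 0 ||
      noise_sd < 0)
    stopf("invalid kinetics spec", class = "nucleopol_parameter_error")
  structure(list(actin_concs = actin_concs, V0 = V0, kcat = kcat,
                 K_actin = K_actin, noise_sd = noise_sd, seed = seed),
            class = "kinetics_sim_spec")
}

#' Simulate a steady-state ATPase titration
#'
#' @param spec a [kinetics_sim_spec()].
#' @return a data.frame of class `kinetics_dataset` with columns `actin`
#'   (uM) and `rate` (s^-1); truth parameters attached as `attr(, "truth")`.
#' @export
simulate_atpase <- function(spec = kinetics_sim_spec()) {
  stopifnot(inherits(spec, "kinetics_sim_spec"))
  a <- spec$actin_concs
  mu <- spec$V0 + spec$kcat * a / (spec$K_actin + a)
  eps <- if (spec$noise_sd > 0)
    with_seed(stream_seed(spec$seed, "atpase"),
              rnorm(length(a), 0, spec$noise_sd))
  else rep(0, length(a))
  out <- data.frame(actin = a, rate = mu + eps)
  class(out) <- c("kinetics_dataset", "data.frame")
  attr(out, "truth") <- list(V0 = spec$V0, kcat = spec$kcat,
                             K_actin = spec$K_actin)
  out
}
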