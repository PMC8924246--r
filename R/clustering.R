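#' DBSCAN parameters for localisation cluster detection
#'
#' The published parameterisation: a molecule is a core point if at least
#' `min_pts = 3` other molecules fall within `epsilon` (the mean
#' localisation precision of the dye: 20 nm for Alexa-647, 30 nm for
#' Alexa-488); a connected group only counts as a cluster if it holds at
#' least `min_cluster_size = 10` localisations; cluster areas are measured
#' on a kernel-density surface smoothed at `smoothing_sigma = 7` nm.
#'
#' @param epsilon search radius (nm); `NULL` defers to the mean precision
#'   of the analysed table.
#' @param min_pts minimum neighbours (excluding the point itself) for core
#'   status.
#' @param min_cluster_size minimum localisations per reported cluster.
#' @param smoothing_sigma KDE bandwidth (nm) for cluster area.
#' @return a list of class `cluster_params`.
#' @export
cluster_params <- function(epsilon = NULL, min_pts = 3,
                           min_cluster_size = 10, smoothing_sigma = 7) {
  if ((!is.null(epsilon) && epsilon <= 0) || min_pts < 1 ||
      min_cluster_size < min_pts || smoothing_sigma <= 0)
    stopf("invalid cluster parameters", class = "nucleopol_parameter_error")
  structure(list(epsilon = epsilon, min_pts = min_pts,
                 min_cluster_size = min_cluster_size,
                 smoothing_sigma = smoothing_sigma),
            class = "cluster_params")
}

#' Density-based cluster labels (DBSCAN)
#'
#' Standard DBSCAN on the 2D coordinates: a point is core iff at least
#' `min_pts` *other* points lie within `epsilon`; clusters are maximal
#' density-connected sets of core points plus the border points they reach;
#' border points join the first cluster that reaches them in deterministic
#' ascending-index scan order; everything else is noise (label 0).
#'
#' @param locs a `loc_table` (or anything with `x`, `y` columns).
#' @param epsilon search radius (nm).
#' @param min_pts minimum neighbour count (excluding self).
#' @return integer vector of labels, 0 for noise.
#' @export
dbscan_labels <- function(locs, epsilon, min_pts = 3) {
  if (epsilon <= 0)
    stopf("epsilon must be positive", class = "nucleopol_parameter_error")
  if (nrow(locs) == 0) return(integer(0))
  cpp_dbscan(locs$x, locs$y, epsilon, as.integer(min_pts))
}

#' Detect clusters in a localisation table
#'
#' Runs [dbscan_labels()], discards connected groups smaller than
#' `min_cluster_size` (their points revert to noise), and computes a
#' centroid, molecule count and smoothed-KDE area per surviving cluster.
#'
#' @param locs a `loc_table`.
#' @param params a [cluster_params()]; when `epsilon` is `NULL` the mean
#'   precision of the table is used, per the published convention of
#'   setting the search radius to the dye's localisation precision.
#' @return an object of class `cluster_set`: list with `labels`
#'   (per-localisation, 0 = noise) and `clusters` (data.frame: `id`, `n`,
#'   `cx`, `cy`, `area`).
#' @examples
#' p <- simulate_clustered(pattern_spec(n_clusters = 30, seed = 4))
#' cs <- detect_clusters(p, cluster_params(epsilon = 20))
#' nrow(cs$clusters)
#' @export
detect_clusters <- function(locs, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  eps <- params$epsilon %||% mean(locs$precision)
  lab <- dbscan_labels(locs, eps, params$min_pts)
  if (length(lab)) {
    sizes <- tabulate(lab)
    small <- which(sizes < params$min_cluster_size)
    lab[lab %in% small] <- 0L
    # renumber surviving clusters in order of first appearance
    keep <- unique(lab[lab > 0])
    lab <- match(lab, keep, nomatch = 0L)
  }
  ids <- sort(unique(lab[lab > 0]))
  clusters <- do.call(rbind, lapply(ids, function(k) {
    sel <- lab == k
    ar <- cluster_area(cbind(locs$x[sel], locs$y[sel]),
                       params$smoothing_sigma)
    data.frame(id = k, n = sum(sel), cx = mean(locs$x[sel]),
               cy = mean(locs$y[sel]), area = as.numeric(ar))
  }))
  if (is.null(clusters))
    clusters <- data.frame(id = integer(0), n = integer(0),
                           cx = numeric(0), cy = numeric(0),
                           area = numeric(0))
  structure(list(labels = lab, clusters = clusters, epsilon = eps,
                 params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters (epsilon = %.1f nm)\n",
              nrow(x$clusters), x$epsilon))
  if (nrow(x$clusters) > 0)
    cat(sprintf("  mean %.1f molecules/cluster, mean area %.0f nm^2\n",
                mean(x$clusters$n), mean(x$clusters$area)))
  invisible(x)
}

#' Area of one cluster from its member coordinates
#'
#' The iso-density contour of a Gaussian kernel-density surface (bandwidth
#' `smoothing_sigma`) at the level that encloses every member point,
#' measured by counting 5 nm grid cells. With fewer than 5 members the KDE
#' contour is ill-defined and the convex hull area is used instead.
#' Collinear or otherwise degenerate member sets return area 0 with a
#' warning and attribute `degenerate = TRUE`.
#'
#' @param members two-column matrix of coordinates (nm).
#' @param smoothing_sigma KDE bandwidth (nm), default 7 nm.
#' @param grid_step evaluation grid step (nm).
#' @return area in nm^2.
#' @examples
#' cluster_area(cbind(c(0, 30, 30, 0), c(0, 0, 40, 40)))  # 30 x 40 hull
#' @export
cluster_area <- function(members, smoothing_sigma = 7, grid_step = 5) {
  members <- as.matrix(members)
  n <- nrow(members)
  if (n < 3) {
    warning("fewer than 3 members: degenerate cluster geometry")
    return(structure(0, degenerate = TRUE))
  }
  hull <- grDevices::chull(members)
  hull_area <- if (length(hull) >= 3)
    polygon_area(members[hull, 1], members[hull, 2]) else 0
  if (hull_area <= 0) {
    warning("collinear cluster members: degenerate geometry, area 0")
    return(structure(0, degenerate = TRUE))
  }
  if (n < 5) return(hull_area)
  s <- smoothing_sigma
  gx <- seq(min(members[, 1]) - 3 * s, max(members[, 1]) + 3 * s,
            by = grid_step)
  gy <- seq(min(members[, 2]) - 3 * s, max(members[, 2]) + 3 * s,
            by = grid_step)
  # separable Gaussian sums: dens[i, j] = sum_p Ax[i, p] * Ay[j, p]
  Ax <- exp(-outer(gx, members[, 1], "-")^2 / (2 * s^2))
  Ay <- exp(-outer(gy, members[, 2], "-")^2 / (2 * s^2))
  dens <- Ax %*% t(Ay)
  # density at the member points themselves sets the enclosing level
  D2 <- outer(members[, 1], members[, 1], "-")^2 +
    outer(members[, 2], members[, 2], "-")^2
  pt_dens <- rowSums(exp(-D2 / (2 * s^2)))
  level <- min(pt_dens)
  sum(dens >= level * (1 - 1e-9)) * grid_step^2
}

#' Per-ROI cluster summary statistics
#'
#' @param set a [detect_clusters()] result.
#' @param locs the `loc_table` the set was computed from.
#' @return a list of class `cluster_summary`: `n_clusters`,
#'   `mean_molecules_per_cluster`, `mean_area` (nm^2) and
#'   `percent_clustered` (% of ROI localisations carrying a cluster
#'   label). With zero clusters the means are `NA` and `undefined_means`
#'   is set.
#' @export
summarize_clusters <- function(set, locs) {
  stopifnot(inherits(set, "cluster_set"))
  if (length(set$labels) != nrow(locs))
    stopf("cluster set does not match the localisation table",
          class = "nucleopol_consistency_error")
  nc <- nrow(set$clusters)
  structure(list(
    n_clusters = nc,
    mean_molecules_per_cluster = if (nc) mean(set$clusters$n) else NA_real_,
    mean_area = if (nc) mean(set$clusters$area) else NA_real_,
    percent_clustered = if (nrow(locs))
      100 * sum(set$labels > 0) / nrow(locs) else 0,
    undefined_means = nc == 0),
    class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(paste0("Cluster summary: %d clusters, %.1f%% of molecules ",
                     "clustered\n"), x$n_clusters, x$percent_clustered))
  if (!x$undefined_means)
    cat(sprintf("  mean %.1f molecules/cluster, mean area %.0f nm^2\n",
                x$mean_molecules_per_cluster, x$mean_area))
  invisible(x)
}

#' Plot a cluster map
#'
#' Localisations rendered as points, cluster members coloured by cluster,
#' noise in grey — the per-ROI cluster-map view.
#'
#' @param x a `cluster_set`.
#' @param locs the matching `loc_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cluster_set <- function(x, locs, ...) {
  lab <- x$labels
  cols <- ifelse(lab == 0, "grey80",
                 grDevices::hcl.colors(max(lab, 1), "Dark 3")[pmax(lab, 1)])
  graphics::plot(locs$x, locs$y, col = cols, pch = 16, cex = 0.3,
                 asp = 1, xlab = "x (nm)", ylab = "y (nm)", ...)
  invisible(x)
}
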