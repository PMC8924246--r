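#' Parameters for degree-of-colocalisation (DoC) scoring
#'
#' Defaults follow the established coordinate-based colocalisation
#' convention: density gradients over 20 nm shells out to 500 nm, a
#' colocalisation threshold of 0.4 on the per-molecule score, and at least
#' 5 colocalised members for a cluster to count as colocalised.
#'
#' @param r_max largest gradient radius (nm).
#' @param r_step radius step (nm); shells are `r_step, 2 r_step, ..., r_max`.
#' @param threshold score threshold in (-1, 1) above which a molecule is
#'   colocalised.
#' @param min_coloc_in_cluster minimum flagged members for a colocalised
#'   cluster.
#' @return a list of class `doc_params`.
#' @export
doc_params <- function(r_max = 500, r_step = 20, threshold = 0.4,
                       min_coloc_in_cluster = 5) {
  if (r_step <= 0 || r_step >= r_max || threshold <= -1 || threshold >= 1 ||
      min_coloc_in_cluster < 1)
    stopf("invalid DoC parameters", class = "nucleopol_parameter_error")
  structure(list(r_max = r_max, r_step = r_step, threshold = threshold,
                 min_coloc_in_cluster = min_coloc_in_cluster),
            class = "doc_params")
}

# Spearman rank correlation with average-rank ties; NA when either vector
# is constant
spearman_rho <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(rank(a), rank(b))
}

doc_one_direction <- function(q, other, radii, r_max) {
  # q, other: lists with x, y. Same-channel counts exclude the query point;
  # other-channel counts exclude exact-coincident detections (the query
  # molecule's own correlate in a duplicated channel), which keeps the
  # perfect-copy identity DoC = 1; the damping distance still sees them.
  n_same <- cpp_radial_counts(q$x, q$y, q$x, q$y, radii, 1L)
  n_other <- cpp_radial_counts(q$x, q$y, other$x, other$y, radii, 2L)
  nnd <- cpp_nn_dist(q$x, q$y, other$x, other$y)
  # The gradient D(r) = N(r)/N(r_max) * r_max^2/r^2 enters only through its
  # ranks, which are invariant to the positive per-vector constants
  # N(r_max) and r_max^2. Ranking N(r)/r^2 directly (one correctly-rounded
  # division of integers) keeps exact rational ties exactly tied, where the
  # chained product would split them by rounding order.
  radii_sq <- radii^2
  n <- length(q$x)
  scores <- numeric(n)
  defined <- logical(n)
  for (i in seq_len(n)) {
    ns <- n_same[i, ]; no <- n_other[i, ]
    if (ns[length(ns)] == 0 || no[length(no)] == 0) next
    d_same <- ns / radii_sq
    d_other <- no / radii_sq
    rho <- spearman_rho(d_same, d_other)
    if (is.na(rho)) next
    defined[i] <- TRUE
    scores[i] <- rho * exp(-nnd[i] / r_max)
  }
  list(scores = scores, defined = defined, nn_dist = nnd)
}

#' Per-molecule degree-of-colocalisation scores between two channels
#'
#' For each molecule, the density gradient of its own channel and of the
#' other channel is evaluated over concentric shells
#' (`D(r) = N(r)/N(r_max) * r_max^2/r^2`); the Spearman rank correlation of
#' the two gradients, damped by `exp(-d / r_max)` with `d` the distance to
#' the nearest other-channel molecule, gives the DoC score in [-1, 1].
#' Scores of 1 mean perfect colocalisation, -1 segregation. Molecules with
#' an empty or constant gradient vector get score 0 and are flagged
#' undefined.
#'
#' @param locs_a,locs_b `loc_table`s for the two channels (same ROI), each
#'   with at least 2 points.
#' @param params a [doc_params()].
#' @return an object of class `doc_result`: per-channel `scores`, `flags`
#'   (score > threshold), `defined`, `nn_dist`, and `percent` colocalised.
#' @examples
#' tc <- simulate_two_channel(two_channel_spec(
#'   pattern_spec(n_clusters = 15, seed = 1),
#'   pattern_spec(n_clusters = 15, seed = 2),
#'   coloc_fraction = 0.5, seed = 3))
#' doc <- doc_scores(tc$a, tc$b)
#' doc$percent_a
#' @export
doc_scores <- function(locs_a, locs_b, params = doc_params()) {
  stopifnot(inherits(params, "doc_params"))
  if (nrow(locs_a) < 2 || nrow(locs_b) < 2)
    stopf("both channels need at least 2 localisations",
          class = "nucleopol_insufficient_data_error")
  radii <- seq(params$r_step, params$r_max, by = params$r_step)
  a <- list(x = locs_a$x, y = locs_a$y)
  b <- list(x = locs_b$x, y = locs_b$y)
  ra <- doc_one_direction(a, b, radii, params$r_max)
  rb <- doc_one_direction(b, a, radii, params$r_max)
  fa <- ra$scores > params$threshold
  fb <- rb$scores > params$threshold
  structure(list(scores_a = ra$scores, scores_b = rb$scores,
                 defined_a = ra$defined, defined_b = rb$defined,
                 nn_dist_a = ra$nn_dist, nn_dist_b = rb$nn_dist,
                 flags_a = fa, flags_b = fb,
                 percent_a = 100 * mean(fa), percent_b = 100 * mean(fb),
                 params = params),
            class = "doc_result")
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf(paste0("DoC result: %.1f%% of channel A and %.1f%% of ",
                     "channel B colocalised (threshold %.2g)\n"),
              x$percent_a, x$percent_b, x$params$threshold))
  und <- sum(!x$defined_a) + sum(!x$defined_b)
  if (und > 0)
    cat(sprintf("  %d molecules with undefined gradients scored 0\n", und))
  invisible(x)
}

#' Colocalised vs non-colocalised cluster breakdown
#'
#' A cluster is colocalised iff it contains at least
#' `params$min_coloc_in_cluster` members whose DoC flag is set. Summaries
#' (cluster count, mean area, mean molecules) are reported per channel for
#' both subpopulations.
#'
#' @param set_a,set_b [detect_clusters()] results for the two channels.
#' @param doc the [doc_scores()] result computed on the same tables.
#' @param params a [doc_params()].
#' @return a data.frame with one row per channel x subpopulation.
#' @export
coloc_cluster_breakdown <- function(set_a, set_b, doc,
                                    params = doc_params()) {
  stopifnot(inherits(doc, "doc_result"))
  if (length(set_a$labels) != length(doc$scores_a) ||
      length(set_b$labels) != length(doc$scores_b))
    stopf("cluster sets and DoC result computed on different tables",
          class = "nucleopol_consistency_error")
  one <- function(set, flags, channel) {
    cl <- set$clusters
    if (nrow(cl) == 0)
      return(data.frame(channel = channel,
                        subpopulation = c("colocalised", "non_colocalised"),
                        n_clusters = 0L, mean_area = NA_real_,
                        mean_molecules = NA_real_))
    n_flagged <- vapply(cl$id, function(k) sum(flags[set$labels == k]),
                        numeric(1))
    is_col <- n_flagged >= params$min_coloc_in_cluster
    sub <- function(sel, name) data.frame(
      channel = channel, subpopulation = name, n_clusters = sum(sel),
      mean_area = if (any(sel)) mean(cl$area[sel]) else NA_real_,
      mean_molecules = if (any(sel)) mean(cl$n[sel]) else NA_real_)
    rbind(sub(is_col, "colocalised"), sub(!is_col, "non_colocalised"))
  }
  rbind(one(set_a, doc$flags_a, "A"), one(set_b, doc$flags_b, "B"))
}
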