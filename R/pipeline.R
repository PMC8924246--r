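#' Run the STORM cluster/colocalisation pipeline
#'
#' Orchestrates the per-ROI analysis exactly as applied per cell: per
#' channel a Ripley curve and its peak, then DBSCAN cluster detection and
#' a cluster summary; with two channels additionally DoC scoring and the
#' colocalised vs non-colocalised cluster breakdown. All tables and the
#' resolved configuration are written to `out_dir` (when given) so a run
#' is self-describing; identical config + seed gives byte-identical
#' outputs.
#'
#' @param config a list (or path to a YAML/JSON file) with elements:
#'   \describe{
#'     \item{locs_a}{`loc_table`, or path to a localisation CSV (required).}
#'     \item{locs_b}{optional second channel, same forms.}
#'     \item{roi}{an [roi_polygon()], or path to an ROI file; default
#'       the bounding box of the data.}
#'     \item{cluster}{[cluster_params()] arguments (list).}
#'     \item{doc}{[doc_params()] arguments (list).}
#'     \item{ripley}{list with `radii` and/or `correction`.}
#'     \item{epsilon_from}{`"precision"` (default) or `"ripley"`: take the
#'       DBSCAN search radius from the dye precision or from the Ripley
#'       peak radius. Recorded in the report either way.}
#'     \item{out_dir}{optional output directory.}
#'   }
#' @return a list of class `storm_report` with per-channel `ripley`,
#'   `peak`, `clusters`, `summary`, plus `doc` and `breakdown` for
#'   two-channel runs, and the resolved `config`.
#' @examples
#' locs <- simulate_clustered(pattern_spec(n_clusters = 25, seed = 5))
#' rep <- run_storm_pipeline(list(locs_a = locs))
#' rep$a$summary
#' @export
run_storm_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[stage %s] %s", name, conditionMessage(e),
            class = "nucleopol_pipeline_error"))
  }
  load_locs <- function(x) {
    if (inherits(x, "loc_table")) x
    else read_localizations(x, dialect = config$dialect %||% "canonical")
  }
  locs_a <- stage("input", load_locs(config$locs_a))
  locs_b <- if (!is.null(config$locs_b))
    stage("input", load_locs(config$locs_b)) else NULL
  roi <- config$roi
  if (is.character(roi)) roi <- stage("roi", read_roi(roi))
  if (is.null(roi)) {
    allx <- c(locs_a$x, locs_b$x); ally <- c(locs_a$y, locs_b$y)
    pad <- 1
    roi <- roi_polygon(c(min(allx) - pad, max(allx) + pad,
                         max(allx) + pad, min(allx) - pad),
                       c(min(ally) - pad, min(ally) - pad,
                         max(ally) + pad, max(ally) + pad))
  }
  ripley_args <- config$ripley %||% list()
  cl_args <- config$cluster %||% list()
  doc_args <- config$doc %||% list()
  epsilon_from <- config$epsilon_from %||% "precision"

  analyse_channel <- function(locs, name) {
    locs <- stage(paste0(name, ":clip"), clip_to_roi(locs, roi))
    curve <- stage(paste0(name, ":ripley"), do.call(ripley_k, c(
      list(locs = locs, roi = roi), ripley_args)))
    pk <- peak_radius(curve)
    params <- do.call(cluster_params, cl_args)
    if (identical(epsilon_from, "ripley") && !is.na(pk))
      params$epsilon <- as.numeric(pk)
    cs <- stage(paste0(name, ":cluster"), detect_clusters(locs, params))
    list(locs = locs, ripley = curve, peak = pk, clusters = cs,
         summary = summarize_clusters(cs, locs))
  }

  report <- list(a = analyse_channel(locs_a, "A"),
                 config = list(epsilon_from = epsilon_from,
                               ripley = ripley_args, cluster = cl_args,
                               doc = doc_args))
  if (!is.null(locs_b)) {
    report$b <- analyse_channel(locs_b, "B")
    dp <- do.call(doc_params, doc_args)
    report$doc <- stage("doc", doc_scores(report$a$locs, report$b$locs, dp))
    report$breakdown <- stage("breakdown", coloc_cluster_breakdown(
      report$a$clusters, report$b$clusters, report$doc, dp))
  }
  class(report) <- "storm_report"
  if (!is.null(config$out_dir))
    write_storm_report(report, config$out_dir)
  report
}

read_run_config <- function(path) {
  if (!file.exists(path))
    stopf("config file not found: %s", path, class = "nucleopol_io_error")
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("the yaml package is needed for YAML configs",
            class = "nucleopol_io_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

write_storm_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(d, f) write.csv(d, file.path(out_dir, f),
                                 row.names = FALSE, quote = FALSE)
  for (ch in intersect(c("a", "b"), names(report))) {
    r <- report[[ch]]
    wr(as.data.frame(r$ripley), sprintf("ripley_%s.csv", ch))
    wr(r$clusters$clusters, sprintf("clusters_%s.csv", ch))
    jsonlite::write_json(
      c(unclass(r$summary), list(peak_radius_nm = as.numeric(r$peak),
                                 epsilon_nm = r$clusters$epsilon)),
      file.path(out_dir, sprintf("summary_%s.json", ch)),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(report$doc)) {
    wr(data.frame(score_a = report$doc$scores_a,
                  flag_a = report$doc$flags_a,
                  defined_a = report$doc$defined_a), "doc_scores_a.csv")
    wr(data.frame(score_b = report$doc$scores_b,
                  flag_b = report$doc$flags_b,
                  defined_b = report$doc$defined_b), "doc_scores_b.csv")
    wr(report$breakdown, "coloc_breakdown.csv")
    jsonlite::write_json(list(percent_a = report$doc$percent_a,
                              percent_b = report$doc$percent_b),
                         file.path(out_dir, "doc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.storm_report <- function(x, ...) {
  cat("STORM pipeline report\n")
  for (ch in intersect(c("a", "b"), names(x))) {
    cat(sprintf("-- channel %s --\n", toupper(ch)))
    print(x[[ch]]$summary)
    pk <- x[[ch]]$peak
    cat(sprintf("  Ripley peak: %s\n",
                if (is.na(pk)) "none" else sprintf("%g nm", pk)))
  }
  if (!is.null(x$doc)) print(x$doc)
  invisible(x)
}

#' Compare a per-ROI statistic between two conditions
#'
#' Two-sided two-sample t test with pooled variance (the plain "two-tailed
#' t test" of figure captions; Welch's form available via `welch = TRUE`).
#' Each ROI contributes one observation. When both groups have zero
#' variance and equal means the test is degenerate and p = 1 is returned
#' with a flag.
#'
#' @param stats_a,stats_b numeric vectors of per-ROI values (n >= 2 each).
#' @param welch use Welch's unequal-variance form.
#' @return a list of class `condition_comparison`: `t`, `p`, `df`,
#'   `mean_a`, `mean_b`, `degenerate`.
#' @examples
#' compare_conditions(c(1, 2, 3), c(11, 12, 13))$p
#' @export
compare_conditions <- function(stats_a, stats_b, welch = FALSE) {
  stats_a <- stats_a[is.finite(stats_a)]
  stats_b <- stats_b[is.finite(stats_b)]
  if (length(stats_a) < 2 || length(stats_b) < 2)
    stopf("each group needs at least 2 observations",
          class = "nucleopol_insufficient_data_error")
  n1 <- length(stats_a); n2 <- length(stats_b)
  if (sd(stats_a) == 0 && sd(stats_b) == 0) {
    same <- isTRUE(all.equal(mean(stats_a), mean(stats_b)))
    return(structure(list(t = if (same) 0 else sign(mean(stats_a) -
                                                      mean(stats_b)) * Inf,
                          p = if (same) 1 else 0, df = n1 + n2 - 2,
                          mean_a = mean(stats_a), mean_b = mean(stats_b),
                          degenerate = TRUE),
                     class = "condition_comparison"))
  }
  ht <- t.test(stats_a, stats_b, var.equal = !welch)
  structure(list(t = unname(ht$statistic), p = ht$p.value,
                 df = unname(ht$parameter),
                 mean_a = mean(stats_a), mean_b = mean(stats_b),
                 degenerate = FALSE),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(paste0("Condition comparison: mean %.3g vs %.3g, ",
                     "t = %.3g (df %.3g), p = %.3g%s\n"),
              x$mean_a, x$mean_b, x$t, x$df, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
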