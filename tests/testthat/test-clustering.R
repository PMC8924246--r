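test_that("two well-separated groups yield exactly two clusters", {
  set.seed(1)
  g1 <- cbind(rnorm(20, 0, 5), rnorm(20, 0, 5))
  g2 <- cbind(rnorm(20, 10000, 5), rnorm(20, 10000, 5))
  locs <- loc_table(c(g1[, 1], g2[, 1]), c(g1[, 2], g2[, 2]))
  lab <- dbscan_labels(locs, epsilon = 20, min_pts = 3)
  expect_setequal(unique(lab), c(1, 2))
})

test_that("core-point status needs min_pts neighbours excluding the point itself", {
  # a point with exactly 2 neighbours within epsilon is not core at min_pts 3
  locs <- loc_table(c(0, 10, -10), c(0, 0, 0))
  lab <- dbscan_labels(locs, epsilon = 15, min_pts = 3)
  expect_true(all(lab == 0))
  # add a third neighbour: the centre becomes core, all join one cluster
  locs4 <- loc_table(c(0, 10, -10, 0), c(0, 0, 0, 10))
  lab4 <- dbscan_labels(locs4, epsilon = 15, min_pts = 3)
  expect_equal(lab4, rep(1L, 4))
})

test_that("DBSCAN labels equal the exhaustive region-query reference", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    ext <- sample(c(200, 500, 1000), 1)
    locs <- loc_table(runif(n, 0, ext), runif(n, 0, ext))
    eps <- sample(c(15, 30, 60), 1)
    got <- dbscan_labels(locs, eps, 3)
    ref <- brute_dbscan(locs, eps, 3)
    expect_identical(canon_labels(got), canon_labels(ref))
  }
})

test_that("row order affects cluster ids only, never memberships", {
  p <- simulate_clustered(pattern_spec(n_clusters = 12,
                                       molecules_per_cluster = 25,
                                       roi = roi_rect(4000), seed = 6))
  set.seed(99)
  perm <- sample(nrow(p))
  p2 <- loc_table(p$x[perm], p$y[perm])
  lab1 <- dbscan_labels(p, 20, 3)
  lab2 <- dbscan_labels(p2, 20, 3)
  # partition of point identities must be identical (row k of p2 is perm[k])
  drop_noise <- function(part) part[names(part) != "0"]
  part1 <- drop_noise(split(seq_len(nrow(p)), lab1))
  part2 <- drop_noise(split(perm, lab2))
  key <- function(part) sort(unname(vapply(part, function(ix)
    paste(sort(ix), collapse = ","), character(1))))
  expect_identical(key(part1), key(part2))
  expect_equal(sum(lab1 == 0), sum(lab2 == 0))
})

test_that("the 10-localisation cluster threshold is enforced exactly", {
  mk_group <- function(n) {
    set.seed(n)
    loc_table(rnorm(n, 0, 3), rnorm(n, 0, 3))
  }
  params <- cluster_params(epsilon = 20, min_pts = 3, min_cluster_size = 10)
  for (n in c(9, 10, 11)) {
    cs <- detect_clusters(mk_group(n), params)
    expect_equal(nrow(cs$clusters), as.integer(n >= 10))
  }
  # sub-threshold groups revert to noise
  cs9 <- detect_clusters(mk_group(9), params)
  expect_true(all(cs9$labels == 0))
})

test_that("detect_clusters never reports a cluster below min_cluster_size", {
  for (seed in 1:5) {
    p <- simulate_clustered(pattern_spec(n_clusters = 30,
                                         molecules_per_cluster = 12,
                                         background_fraction = 0.3,
                                         roi = roi_rect(5000), seed = seed))
    cs <- detect_clusters(p, cluster_params(epsilon = 20))
    if (nrow(cs$clusters)) expect_gte(min(cs$clusters$n), 10)
    # labels and cluster table agree
    expect_equal(sort(unique(cs$labels[cs$labels > 0])),
                 sort(cs$clusters$id))
    expect_equal(as.vector(table(cs$labels[cs$labels > 0])[
      as.character(cs$clusters$id)]), cs$clusters$n)
  }
})

test_that("epsilon defaults to the mean precision of the dye table", {
  p <- simulate_clustered(pattern_spec(n_clusters = 10, roi = roi_rect(4000),
                                       seed = 3))
  cs <- detect_clusters(p)
  expect_equal(cs$epsilon, mean(p$precision))
})

test_that("hull fallback gives the exact rectangle area for 4 corner points", {
  expect_equal(cluster_area(cbind(c(0, 30, 30, 0), c(0, 0, 40, 40))), 1200)
})

test_that("collinear members are degenerate with area 0", {
  expect_warning(a <- cluster_area(cbind(c(0, 10, 20), c(0, 0, 0))))
  expect_equal(as.numeric(a), 0)
  expect_true(attr(a, "degenerate"))
})

test_that("KDE-contour areas stay within a sane envelope of the hull area", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- cbind(rnorm(30, 0, 15), rnorm(30, 0, 15))
    hull <- m[grDevices::chull(m), ]
    hull_area <- abs(sum(hull[, 1] * c(hull[-1, 2], hull[1, 2]) -
                           c(hull[-1, 1], hull[1, 1]) * hull[, 2])) / 2
    a <- cluster_area(m, smoothing_sigma = 7)
    expect_gte(a, 0.5 * hull_area)
    expect_lte(a, 4 * hull_area)
  }
})

test_that("cluster summaries count the clustered percentage correctly", {
  # every point in one tight cluster
  set.seed(2)
  p <- loc_table(rnorm(20, 0, 3), rnorm(20, 0, 3))
  cs <- detect_clusters(p, cluster_params(epsilon = 20))
  s <- summarize_clusters(cs, p)
  expect_equal(s$percent_clustered, 100)
  expect_equal(s$n_clusters, 1)

  # half the points clustered, half isolated far away
  iso <- loc_table(seq(1e5, by = 1e4, length.out = 20), rep(0, 20))
  both <- loc_table(c(p$x, iso$x), c(p$y, iso$y))
  cs2 <- detect_clusters(both, cluster_params(epsilon = 20))
  s2 <- summarize_clusters(cs2, both)
  expect_equal(s2$percent_clustered, 50)

  # zero clusters: flagged undefined means
  s3 <- summarize_clusters(detect_clusters(iso, cluster_params(epsilon = 20)),
                           iso)
  expect_equal(s3$n_clusters, 0)
  expect_true(s3$undefined_means)
})

test_that("cluster parameter invariants are enforced", {
  expect_error(cluster_params(epsilon = -1), class = "nucleopol_parameter_error")
  expect_error(cluster_params(min_pts = 5, min_cluster_size = 3),
               class = "nucleopol_parameter_error")
})
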