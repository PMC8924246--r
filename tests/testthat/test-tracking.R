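test_that("MSD of simple hand-computable tracks is exact", {
  # immobile
  tr0 <- data.frame(frame = 1:5, t = (1:5) * 0.032, x = 1, y = 2, z = 3)
  expect_true(all(compute_msd(tr0)$msd == 0))
  # constant-velocity 1 um/frame: msd(k) = k^2
  tr <- data.frame(frame = 1:3, t = (1:3) * 0.032, x = c(0, 1, 2), y = 0,
                   z = 0)
  m <- compute_msd(tr)
  expect_equal(m$msd, c(1, 4))
  expect_equal(m$n_pairs, c(2L, 1L))
  expect_equal(m$tau, c(0.032, 0.064))
})

test_that("MSD equals the brute-force all-pairs computation, gaps excluded", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    frames <- sort(sample(1:(n * 2), n))
    tr <- data.frame(frame = frames, t = frames * 0.032,
                     x = cumsum(rnorm(n)), y = cumsum(rnorm(n)),
                     z = cumsum(rnorm(n)))
    m <- compute_msd(tr)
    expect_equal(m$msd, brute_msd(tr), tolerance = 1e-9)
  }
})

test_that("noiseless power-law curves invert exactly", {
  tau <- (1:20) * 0.032
  curve <- structure(data.frame(lag = 1:20, tau = tau, msd = 6 * 0.4 * tau,
                                n_pairs = 20L),
                     class = c("msd_curve", "data.frame"), dims = 3L)
  fit <- fit_anomalous(curve)
  expect_equal(fit$D, 0.4, tolerance = 1e-12)
  expect_equal(fit$alpha, 1, tolerance = 1e-12)
  # subdiffusive closed form, 2D prefactor
  curve2 <- structure(data.frame(lag = 1:20, tau = tau,
                                 msd = 4 * 0.07 * tau^0.6, n_pairs = 20L),
                      class = c("msd_curve", "data.frame"), dims = 2L)
  fit2 <- fit_anomalous(curve2)
  expect_equal(fit2$D, 0.07, tolerance = 1e-12)
  expect_equal(fit2$alpha, 0.6, tolerance = 1e-12)
  expect_equal(fit2$mobility_class, "static")
})

test_that("mobility classes are a pure function of D with closed right boundaries", {
  expect_equal(classify_mobility(c(0, 0.05, 0.1, 1, 5, 5.01)),
               c("static", "static", "diffusive", "diffusive", "diffusive",
                 "hypermobile"))
  # all-zero MSD: D = 0, static, alpha undefined
  curve <- structure(data.frame(lag = 1:5, tau = (1:5) * 0.032, msd = 0,
                                n_pairs = 5L),
                     class = c("msd_curve", "data.frame"), dims = 3L)
  fit <- fit_anomalous(curve)
  expect_equal(fit$D, 0)
  expect_equal(fit$mobility_class, "static")
  expect_true(is.na(fit$alpha))
})

test_that("ensemble MSD of simulated Brownian tracks follows 6 D tau", {
  tr <- simulate_tracks(track_sim_spec(n_tracks = 300, frames = 30, D = 0.5,
                                       alpha = 1, dims = 3,
                                       loc_error_sigma = 0, seed = 31))
  ids <- unique(tr$track_id)
  msd1 <- mean(vapply(ids, function(id) {
    t1 <- tr[tr$track_id == id, ]
    compute_msd(t1)$msd[1]
  }, numeric(1)))
  expect_equal(msd1, 6 * 0.5 * 0.032, tolerance = 0.05)
})

test_that("track fits recover generator truth within the stated bias bounds", {
  tr <- simulate_tracks(track_sim_spec(n_tracks = 100, frames = 100, D = 0.4,
                                       alpha = 1, loc_error_sigma = 0.02,
                                       seed = 17))
  fits <- fit_tracks(tr)
  expect_lt(abs(mean(fits$D) - 0.4) / 0.4, 0.1)
  expect_lt(abs(mean(fits$alpha) - 1), 0.1)
  # subdiffusive recovery at the median
  tr2 <- simulate_tracks(track_sim_spec(n_tracks = 100, frames = 100,
                                        D = 0.4, alpha = 0.5,
                                        loc_error_sigma = 0.02, seed = 18))
  fits2 <- fit_tracks(tr2)
  expect_lt(abs(median(fits2$alpha) - 0.5), 0.1)
})

test_that("mobility summaries split static and mobile correctly", {
  fits <- data.frame(track_id = 1:4, D = c(0.01, 0.02, 1, 8),
                     alpha = 1, class = c("static", "static", "diffusive",
                                          "hypermobile"),
                     rss = 0, fit_lags = 3, fit_failed = FALSE)
  s <- summarize_mobility(fits)
  expect_equal(s$static_fraction, 0.5)
  expect_equal(s$mobile_fraction, 0.5)
  # hypermobile excluded from mean D by default, included on request
  expect_equal(s$mean_D, mean(c(0.01, 0.02, 1)))
  expect_equal(summarize_mobility(fits, include_hypermobile = TRUE)$mean_D,
               mean(c(0.01, 0.02, 1, 8)))
  # all static
  expect_equal(summarize_mobility(fits[1:2, ])$static_fraction, 1)
  # zero successful fits
  fits$fit_failed <- TRUE
  expect_true(summarize_mobility(fits)$empty)
})

test_that("greedy linking respects the displacement cap and track minimum", {
  # steady 0.1 um/frame drift: one unbroken track
  det <- data.frame(frame = 1:15, x = (1:15) * 0.1, y = 0, z = 0)
  tr <- link_tracks(det, max_disp = 0.4, min_frames = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 15)

  # a 0.5 um jump breaks the track; both halves too short at min 10
  det2 <- data.frame(frame = 1:15, x = c((1:8) * 0.1, 5 + (9:15) * 0.1),
                     y = 0, z = 0)
  tr2 <- link_tracks(det2, max_disp = 0.4, min_frames = 10)
  expect_equal(nrow(tr2), 0)
  tr2b <- link_tracks(det2, max_disp = 0.4, min_frames = 5)
  expect_equal(length(unique(tr2b$track_id)), 2)

  # two particles always far apart: two tracks, no identity swap
  det3 <- rbind(data.frame(frame = rep(1:12, each = 1), x = (1:12) * 0.05,
                           y = 0, z = 0),
                data.frame(frame = 1:12, x = (1:12) * 0.05, y = 10, z = 0))
  tr3 <- link_tracks(det3, max_disp = 0.4, min_frames = 10)
  expect_equal(length(unique(tr3$track_id)), 2)
  ys <- tapply(tr3$y, tr3$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))
})
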