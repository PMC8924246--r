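test_that("CSR generator is uniform, seeded and handles n = 0", {
  expect_equal(nrow(simulate_csr(0, seed = 1)), 0)
  roi <- roi_rect(10000)
  p1 <- simulate_csr(1e4, roi, seed = 42)
  p2 <- simulate_csr(1e4, roi, seed = 42)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  # empirical intensity in a sub-window within 3 binomial standard errors
  n <- nrow(p1)
  frac <- mean(p1$x < 5000)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(frac - 0.5), 3 * se)
  expect_true(all(points_in_roi(p1$x, p1$y, roi)))
})

test_that("clustered generator matches its Thomas-process bookkeeping", {
  spec <- pattern_spec(n_clusters = 100, molecules_per_cluster = 30,
                       background_fraction = 0.2, seed = 9)
  p <- simulate_clustered(spec)
  truth <- attr(p, "truth")
  expect_equal(length(truth$labels), nrow(p))
  expect_equal(nrow(truth$centers), 100)
  # expected total: n_clusters * mpc / (1 - bg), within Poisson noise
  expected <- 100 * 30 / 0.8
  expect_lt(abs(nrow(p) - expected) / expected, 5 * sqrt(3000) / 3000)
  # realised background share equals the spec up to rounding
  expect_equal(mean(truth$labels == 0), 0.2, tolerance = 0.01)
  # determinism
  p2 <- simulate_clustered(spec)
  expect_identical(as.data.frame(p), as.data.frame(p2))
})

test_that("vanishing scatter and background collapse clusters to their centres", {
  spec <- pattern_spec(n_clusters = 10, molecules_per_cluster = 20,
                       cluster_sigma = 1e-9, background_fraction = 0,
                       precision_sigma = 0, seed = 2)
  p <- simulate_clustered(spec)
  truth <- attr(p, "truth")
  d <- sqrt((p$x - truth$centers$x[truth$labels])^2 +
              (p$y - truth$centers$y[truth$labels])^2)
  expect_lt(max(d), 1e-6)
})

test_that("invalid pattern specifications are rejected", {
  expect_error(pattern_spec(background_fraction = 1),
               class = "nucleopol_parameter_error")
  expect_error(pattern_spec(cluster_sigma = 0),
               class = "nucleopol_parameter_error")
  expect_error(track_sim_spec(alpha = 0), class = "nucleopol_parameter_error")
  expect_error(track_sim_spec(mixture = list(list(weight = 0.6, D = 1),
                                             list(weight = 0.6, D = 2))),
               class = "nucleopol_parameter_error")
  expect_error(kinetics_sim_spec(K_actin = 0),
               class = "nucleopol_parameter_error")
})

test_that("two-channel generator records its colocalised share exactly", {
  mk <- function(frac) simulate_two_channel(two_channel_spec(
    pattern_spec(n_clusters = 20, molecules_per_cluster = 15, seed = 1),
    pattern_spec(n_clusters = 20, molecules_per_cluster = 15, seed = 2),
    coloc_fraction = frac, displacement_sigma = 0, seed = 3))
  tc <- mk(0.5)
  expect_equal(attr(tc$b, "truth")$shared_share, 0.5)
  expect_equal(sum(attr(tc$b, "truth")$shared), 10)
  # full colocalisation with zero displacement: B centres sit on A centres
  tc1 <- mk(1)
  ca <- attr(tc1$a, "truth")$centers
  cb <- attr(tc1$b, "truth")$centers
  nn <- sapply(seq_len(nrow(cb)), function(i)
    min(sqrt((ca$x - cb$x[i])^2 + (ca$y - cb$y[i])^2)))
  expect_equal(max(nn), 0)
  # zero colocalisation: no shared centres recorded
  expect_equal(sum(attr(mk(0)$b, "truth")$shared), 0)
})

test_that("track generator obeys the Brownian closed form and mixture bookkeeping", {
  # D = 0, no noise: frozen tracks
  tr0 <- simulate_tracks(track_sim_spec(n_tracks = 3, frames = 10, D = 0,
                                        loc_error_sigma = 0, seed = 1))
  expect_equal(max(abs(diff(tr0$x))), 0)

  # alpha = 1, dims = 2: per-step variance per axis = 2 D dt
  spec <- track_sim_spec(n_tracks = 300, frames = 50, D = 0.5, alpha = 1,
                         dims = 2, loc_error_sigma = 0, seed = 8)
  tr <- simulate_tracks(spec)
  steps <- unlist(lapply(split(tr$x, tr$track_id), diff))
  v <- var(steps)
  expected <- 2 * 0.5 * 0.032
  expect_equal(v, expected, tolerance = 0.05)

  # mixture static share recorded exactly
  trm <- simulate_tracks(track_sim_spec(n_tracks = 50, frames = 20, seed = 4,
    mixture = list(list(weight = 0.5, D = 0.01, alpha = 1),
                   list(weight = 0.5, D = 1, alpha = 1))))
  truth <- attr(trm, "truth")
  expect_equal(mean(truth$class == "static"), 0.5)
  expect_identical(as.data.frame(simulate_tracks(spec)), as.data.frame(tr))
})

test_that("fBm tracks reproduce the anomalous MSD power law at the ensemble level", {
  spec <- track_sim_spec(n_tracks = 300, frames = 40, D = 0.2, alpha = 0.5,
                         dims = 2, loc_error_sigma = 0, seed = 5)
  tr <- simulate_tracks(spec)
  # ensemble MSD at lags 1 and 4: ratio should be 4^alpha = 2
  by_track <- split(seq_len(nrow(tr)), tr$track_id)
  msd_at <- function(k) mean(unlist(lapply(by_track, function(ix) {
    x <- tr$x[ix]; y <- tr$y[ix]
    n <- length(x)
    (x[(1 + k):n] - x[1:(n - k)])^2 + (y[(1 + k):n] - y[1:(n - k)])^2
  })))
  expect_equal(msd_at(4) / msd_at(1), 4^0.5, tolerance = 0.1)
  expect_equal(msd_at(1), 2 * 2 * 0.2 * 0.032^0.5, tolerance = 0.1)
})

test_that("ATPase generator evaluates the kinetic model exactly when noiseless", {
  d0 <- simulate_atpase(kinetics_sim_spec(actin_concs = c(0, 3, 10, 30),
                                          V0 = 0.1, kcat = 6, K_actin = 3,
                                          noise_sd = 0))
  expect_equal(d0$rate[1], 0.1)                  # basal at zero actin
  expect_equal(d0$rate[2], 0.1 + 6 / 2)          # half-maximal at K_actin
  expect_equal(d0$rate[4], 0.1 + 6 * 30 / 33)
})
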