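test_that("gaze precision is RMS scatter about the cluster mean", {
  cl <- fixation_cluster(rep(1, 10), rep(2, 10), 1, 2)
  expect_equal(gaze_precision(cl), 0)

  cl <- fixation_cluster(c(-1, 1), c(0, 0), 0, 0)
  expect_equal(gaze_precision(cl), 1)

  cl <- fixation_cluster(c(-1, 1, 1, -1), c(-1, -1, 1, 1), 0, 0)
  expect_equal(gaze_precision(cl), sqrt(2))

  expect_error(fixation_cluster(1, 1, 0, 0), "length")
})

test_that("gaze accuracy is the mean-to-target angular distance", {
  cl <- fixation_cluster(c(0.9, 1.1), c(0.2, -0.2), 1, 0)
  expect_equal(as.numeric(gaze_accuracy(cl)), 0)

  cl <- fixation_cluster(c(1.9, 2.1), c(0, 0), 1, 0)
  expect_equal(as.numeric(gaze_accuracy(cl)), 1)

  cl <- fixation_cluster(c(3, 3), c(4, 4), 0, 0)
  expect_equal(as.numeric(gaze_accuracy(cl)), 5)
  expect_equal(attr(gaze_accuracy(cl), "components"), c(x = 3, y = 4))
})

test_that("precision/accuracy invariances under rigid motion", {
  set.seed(61)
  x <- rnorm(50, 2, 0.3); y <- rnorm(50, -1, 0.3)
  cl <- fixation_cluster(x, y, 2, -1)
  p0 <- gaze_precision(cl)
  a0 <- as.numeric(gaze_accuracy(cl))
  th <- 0.7
  xr <- cos(th) * x - sin(th) * y
  yr <- sin(th) * x + cos(th) * y
  expect_equal(gaze_precision(fixation_cluster(xr + 5, yr - 3, 0, 0)), p0)
  # common translation of cluster and target preserves accuracy magnitude
  expect_equal(as.numeric(gaze_accuracy(fixation_cluster(x + 5, y - 3, 7, -4))),
               a0)
})

test_that("two-sigma dynamic accuracy fits a lognormal to the errors", {
  expect_equal(two_sigma_dynamic_accuracy(rep(2.5, 30)), 2.5)

  set.seed(62)
  e <- rlnorm(10000, meanlog = 0, sdlog = 0.5)
  expect_equal(two_sigma_dynamic_accuracy(e), exp(1), tolerance = 0.03)

  # scale equivariance
  expect_equal(two_sigma_dynamic_accuracy(3 * e),
               3 * two_sigma_dynamic_accuracy(e), tolerance = 1e-9)

  expect_error(two_sigma_dynamic_accuracy(c(e[1:30], -1, 0)),
               "non-positive errors at indices: 31, 32")
  expect_error(two_sigma_dynamic_accuracy(e[1:10]), "at least 20")
})

test_that("FOV uncertainty evaluates its closed form", {
  expect_equal(fov_uncertainty(0.5, 1, 0, 0), 0)
  expect_equal(fov_uncertainty(0.5, 1, 0.01, 0.02), 0.01331, tolerance = 1e-4)
  # homogeneity in the sigmas
  expect_equal(fov_uncertainty(0.5, 1, 0.02, 0.04),
               2 * fov_uncertainty(0.5, 1, 0.01, 0.02), tolerance = 1e-12)
  expect_error(fov_uncertainty(2, 1, 0.001, 0.001, sigma_ld = 1), "radicand")
})

test_that("blink-rate error is the literal miss fraction", {
  expect_equal(blink_rate_error(0, 0, 12), 0)
  expect_equal(blink_rate_error(1, 1, 10), 0.2)
  expect_equal(blink_rate_error(3, 0, 6), 0.5)
  expect_error(blink_rate_error(1, 1, 0), "positive")
})

test_that("validity reports RMS error and product-moment correlation", {
  p <- paired_series(c(1, 2, 3), c(1, 2, 3))
  v <- validity(p)
  expect_equal(v$rms_error, 0)
  expect_equal(v$cc, 1)

  x <- c(-2, -1, 0, 1, 2)
  v <- validity(paired_series(x, -x))
  expect_equal(v$cc, -1)

  v <- validity(paired_series(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(v$rms_error, sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(round(v$rms_error, 4), 0.5774)

  v <- validity(paired_series(c(1, 1, 1), c(1, 2, 3)))
  expect_true(is.na(v$cc))
  expect_match(attr(v, "cc_reason"), "zero variance")
})

test_that("validity invariances: triangle bound and affine rescaling of cc", {
  set.seed(63)
  rms <- function(a, b) sqrt(mean((a - b)^2))
  for (rep in 1:20) {
    a <- rnorm(40); b <- rnorm(40); c <- rnorm(40)
    expect_lte(rms(a, c), rms(a, b) + rms(b, c) + 1e-12)
  }
  a <- rnorm(40); b <- a + rnorm(40, 0, 0.5)
  cc0 <- validity(paired_series(a, b))$cc
  expect_equal(validity(paired_series(a, 3 * b + 7))$cc, cc0, tolerance = 1e-12)
})

test_that("nearest-timestamp alignment drops unmatched samples", {
  ref <- data.frame(t = seq(0, 10, by = 1), value = 1:11)
  meas <- data.frame(t = seq(0.05, 6, by = 1), value = 101:106)
  p <- paired_series(ref, meas, max_lag = 0.5)
  expect_equal(nrow(p), 6L)
  expect_equal(attr(p, "n_dropped"), 5L)
  expect_match(attr(p, "alignment"), "nearest-timestamp")
})

test_that("synthetic sensor pairs recover injected bias and noise", {
  set.seed(64)
  truth <- data.frame(t = seq(0, 99), value = 70 + 3 * sin(seq(0, 99) / 10))
  p <- simulate_sensor_pair(truth, bias = 0, noise_sd = 0, latency = 0)
  v <- validity(p)
  expect_equal(v$rms_error, 0)
  expect_equal(v$cc, 1)

  p <- simulate_sensor_pair(truth, bias = -2.5, noise_sd = 0)
  expect_equal(validity(p)$rms_error, 2.5, tolerance = 1e-12)

  truth <- data.frame(t = seq_len(10000), value = rep(70, 10000))
  p <- simulate_sensor_pair(truth, bias = 0, noise_sd = 1.2, seed = 3)
  expect_equal(validity(p)$rms_error, 1.2, tolerance = 0.03)

  # gaze cluster parameter recovery: bias within 3 sigma/sqrt(n), sd within 10%
  set.seed(65)
  n <- 1000; b <- c(0.8, -0.6); s <- 0.5
  cl <- fixation_cluster(5 + b[1] + rnorm(n, 0, s / sqrt(2)),
                         -2 + b[2] + rnorm(n, 0, s / sqrt(2)), 5, -2)
  expect_equal(as.numeric(gaze_accuracy(cl)), sqrt(sum(b^2)),
               tolerance = 3 * s / sqrt(n))
  expect_equal(gaze_precision(cl), s, tolerance = 0.1)
})

test_that("filter-then-validate protocol runs end to end on synthetic pairs", {
  set.seed(66)
  t <- seq(0, 120, by = 0.25)
  hr_true <- 70 + 4 * sin(2 * pi * t / 60)
  noisy <- hr_true + 0.8 * sin(2 * pi * 1.5 * t)  # high-frequency artefact
  meas <- simulate_sensor_pair(data.frame(t = t, value = noisy),
                               bias = 0.5, noise_sd = 0.2, seed = 7)
  filtered <- butterworth_chain(meas$measured, fs = 4, lowpass_hz = 0.2)
  rep <- characterisation_report(
    pair = paired_series(data.frame(t = t, value = hr_true),
                         data.frame(t = t, value = filtered)))
  expect_lt(rep$rms_error, 1)
  expect_gt(rep$cc, 0.95)
})
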