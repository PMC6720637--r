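test_that("blink detection separates blinks from tracking loss", {
  s <- make_stream(duration = 5, fs = 100)
  expect_equal(nrow(detect_blinks(s)), 0L)

  s <- make_stream(duration = 5, fs = 100, invalid = list(c(1.0, 1.15)))
  b <- detect_blinks(s, max_gap = 0.5)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 0.15, tolerance = 1e-9)
  expect_true(b$t_start >= s$t[1] && b$t_end <= s$t[nrow(s)])

  s <- make_stream(duration = 5, fs = 100, invalid = list(c(1.0, 3.0)))
  expect_equal(nrow(detect_blinks(s, max_gap = 0.5)), 0L)

  expect_error(detect_blinks(make_stream(0.01, 100)[0, ]), "no samples")
})

test_that("blink events are ordered and non-overlapping", {
  s <- make_stream(duration = 10, fs = 100,
                   invalid = list(c(1, 1.1), c(2, 2.2), c(5, 5.05)))
  b <- detect_blinks(s)
  expect_equal(nrow(b), 3L)
  expect_true(all(diff(b$t_start) > 0))
  expect_true(all(b$t_end[-nrow(b)] <= b$t_start[-1L]))
})

test_that("dispersion-threshold fixation detection matches hand cases", {
  # stationary input: one fixation covering the record
  s <- make_stream(duration = 1, fs = 100)
  f <- detect_fixations(s, d_max = 1, min_duration = 0.1)
  expect_equal(nrow(f), 1L)
  expect_equal(f$duration, 1.0)
  expect_equal(c(f$centroid_x, f$centroid_y), c(0, 0))
  expect_equal(f$dispersion, 0)

  # two stationary epochs joined by a ramp -> exactly two fixations
  s <- make_steps_stream(rbind(c(0, 0), c(10, 0)), hold = 0.4, ramp = 0.05)
  f <- detect_fixations(s, d_max = 1, min_duration = 0.1)
  expect_equal(nrow(f), 2L)
  expect_equal(f$centroid_x, c(0, 10), tolerance = 0.05)
  expect_equal(f$centroid_y, c(0, 0))

  # smooth drift at 5 deg/s: every 0.5 s window spans 2.5 deg
  t <- seq(0, 2, by = 0.01)
  s <- gaze_stream(t, 5 * t, 0, sampling_rate = 100)
  expect_equal(nrow(detect_fixations(s, d_max = 1, min_duration = 0.5)), 0L)

  # all samples invalid: empty result, not an error
  s <- make_stream(duration = 1, fs = 100, invalid = list(c(0, 2)))
  expect_equal(nrow(detect_fixations(s)), 0L)
})

test_that("fixation detection equals the brute-force window-growing oracle", {
  set.seed(302)
  for (rep in 1:20) {
    # random piecewise-stationary scan with tremor and occasional blinks
    pts <- cbind(runif(4, -15, 15), runif(4, -10, 10))
    s <- make_steps_stream(pts, hold = runif(1, 0.15, 0.5),
                           ramp = 0.04, fs = 100)
    s$x <- s$x + rnorm(nrow(s), 0, 0.15)
    s$y <- s$y + rnorm(nrow(s), 0, 0.15)
    if (rep %% 3 == 0) s$valid[sample(nrow(s), 20)] <- FALSE
    s <- s[seq_len(min(nrow(s), 500L)), ]
    class(s) <- c("gaze_stream", "data.frame")
    f <- detect_fixations(s, d_max = 1, min_duration = 0.1)
    orc <- oracle_fixations(s, d_max = 1, min_duration = 0.1)
    expect_equal(nrow(f), length(orc))
    if (length(orc)) {
      expect_equal(f$t_start, vapply(orc, function(o) s$t[o["i"]], numeric(1)))
      expect_equal(f$t_end, vapply(orc, function(o) s$t[o["j"]], numeric(1)))
    }
  }
})

test_that("time to first fixation subtracts the reference instant", {
  f <- data.frame(t_start = c(0.35, 1.0), t_end = c(0.8, 1.4),
                  duration = c(0.45, 0.4))
  class(f) <- c("fixation_events", "data.frame")
  expect_equal(time_to_first_fixation(f, t0 = 0.35), 0)
  expect_equal(time_to_first_fixation(f, t0 = 0), 0.35)
  f2 <- f; f2$t_start <- f2$t_start + 1.15
  expect_equal(time_to_first_fixation(f2, t0 = 1.0), 0.5)
  expect_error(time_to_first_fixation(f[0, ], 0), "no fixations")
})

test_that("saccade detection applies velocity threshold and duration bounds", {
  # stationary stream: no saccades
  expect_equal(nrow(detect_saccades(make_stream(1, fs = 250))), 0L)

  # 40 ms linear jump of 10 deg at 250 Hz: velocity 250 deg/s on the ramp
  fs <- 250
  xs <- c(rep(0, 100), seq(1, 10, length.out = 10), rep(10, 100))
  t <- (seq_along(xs) - 1) / fs
  s <- gaze_stream(t, xs, 0, sampling_rate = fs)
  sac <- detect_saccades(s, v_threshold = 30)
  expect_equal(nrow(sac), 1L)
  expect_equal(sac$amplitude, 10, tolerance = 0.01)
  expect_equal(sac$peak_velocity, 250, tolerance = 0.01)
  # run includes the half-velocity boundary samples; frozen from the
  # finite-difference oracle
  expect_gt(sac$mean_velocity, 200)
  expect_lte(sac$mean_velocity, 250)
  expect_true(sac$peak_velocity >= sac$mean_velocity)
  expect_true(sac$duration >= 0.03 && sac$duration <= 0.08)

  # 200 ms smooth-pursuit ramp at 50 deg/s: above threshold, too long
  xs <- c(rep(0, 100), seq(0.2, 10, by = 0.2), rep(10, 100))
  t <- (seq_along(xs) - 1) / fs
  s <- gaze_stream(t, xs, 0, sampling_rate = fs)
  expect_equal(nrow(detect_saccades(s, v_threshold = 30)), 0L)

  expect_warning(detect_saccades(make_stream(1, fs = 50)), "low-confidence")
})

test_that("no sample is interior to both a fixation and a saccade", {
  set.seed(77)
  rois <- roi_layout(c("A", "B", "C"), x_min = c(-15, -5, 5),
                     x_max = c(-5, 5, 15), y_min = -5, y_max = 5)
  sim <- simulate_gaze(rois, duration = 20, blink_rate = 0, seed = 9)
  fix <- detect_fixations(sim$stream)
  sac <- detect_saccades(sim$stream)
  expect_gt(nrow(fix), 0)
  for (k in seq_len(nrow(sac))) {
    inside_sac <- sim$stream$t > sac$t_start[k] & sim$stream$t < sac$t_end[k]
    for (m in seq_len(nrow(fix))) {
      inside_fix <- sim$stream$t > fix$t_start[m] & sim$stream$t < fix$t_end[m]
      expect_false(any(inside_sac & inside_fix))
    }
  }
})

test_that("explore/exploit ratio counts events over long fixations", {
  f <- data.frame(duration = c(0.6, 0.7, 0.8, 0.2, 0.3))
  class(f) <- c("fixation_events", "data.frame")
  s <- data.frame(t_start = 1:4)
  expect_equal(explore_exploit_ratio(f, s, 0.5), (4 + 5) / 3)
  f_all_long <- data.frame(duration = rep(1, 5))
  expect_equal(explore_exploit_ratio(f_all_long, s[0, , drop = FALSE], 0.5), 1)
  f_short <- data.frame(duration = rep(0.1, 5))
  expect_error(explore_exploit_ratio(f_short, s, 0.5), "undefined ratio")
})
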