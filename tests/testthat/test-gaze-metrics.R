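fix_at <- function(xy) {
  f <- data.frame(t_start = seq_len(nrow(xy)) - 1 + 0.1,
                  t_end = seq_len(nrow(xy)) - 1 + 0.5,
                  duration = 0.4,
                  centroid_x = xy[, 1], centroid_y = xy[, 2],
                  dispersion = 0.1)
  class(f) <- c("fixation_events", "data.frame")
  f
}

three_rois <- roi_layout(c("A", "B", "C"),
                         x_min = c(0, 10, 20), x_max = c(5, 15, 25),
                         y_min = 0, y_max = 5)

test_that("dwell segmentation run-length encodes ROI visits", {
  # A, A, B -> two dwells
  f <- fix_at(rbind(c(1, 1), c(2, 2), c(12, 1)))
  d <- segment_dwells(f, three_rois)
  expect_equal(d$roi_id, c("A", "B"))
  expect_equal(d$n_fixations, c(2L, 1L))
  expect_equal(d$t_start[1], f$t_start[1])
  expect_equal(d$t_end[1], f$t_end[2])

  # single fixation -> one dwell
  d1 <- segment_dwells(fix_at(rbind(c(1, 1))), three_rois)
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$n_fixations, 1L)

  # A, outside, A -> two separate A dwells
  f <- fix_at(rbind(c(1, 1), c(8, 1), c(2, 2)))
  d <- segment_dwells(f, three_rois)
  expect_equal(d$roi_id, c("A", "A"))
  expect_equal(d$n_fixations, c(1L, 1L))
})

test_that("ROI boundaries are closed on min edges, open on max edges", {
  rois <- roi_layout(c("L", "R"), x_min = c(0, 5), x_max = c(5, 10),
                     y_min = 0, y_max = 5)
  expect_equal(cogniphys:::assign_roi(5, 1, rois), "R")
  expect_equal(cogniphys:::assign_roi(0, 0, rois), "L")
  expect_true(is.na(cogniphys:::assign_roi(10, 1, rois)))
  expect_error(roi_layout(c("a", "b"), x_min = c(0, 3), x_max = c(5, 8),
                          y_min = 0, y_max = 5), "overlap")
})

test_that("transition matrix is row-stochastic with a zero diagonal", {
  dw <- function(ids) {
    d <- data.frame(roi_id = ids, t_start = seq_along(ids),
                    t_end = seq_along(ids) + 0.5,
                    n_fixations = rep(1L, length(ids)))
    class(d) <- c("dwell_events", "data.frame")
    d
  }
  tm <- transition_matrix(dw(c("A", "B", "A", "B")), three_rois)
  expect_equal(tm$P["A", "B"], 1)
  expect_equal(tm$P["B", "A"], 1)
  expect_equal(diag(tm$P), c(A = 0, B = 0, C = 0))

  expect_true(all(transition_matrix(dw("A"), three_rois)$P == 0))

  tm <- transition_matrix(dw(c("A", "B", "C", "A", "B", "C")), three_rois)
  expect_equal(tm$P["A", "B"], 1)
  expect_equal(tm$P["B", "C"], 1)
  expect_equal(tm$P["C", "A"], 1)

  # property: random dwell sequences
  set.seed(41)
  for (rep in 1:25) {
    ids <- sample(c("A", "B", "C"), 30, replace = TRUE)
    ids <- ids[c(TRUE, diff(match(ids, c("A", "B", "C"))) != 0)]  # no repeats
    tm <- transition_matrix(dw(ids), three_rois)
    expect_equal(diag(tm$P), c(A = 0, B = 0, C = 0))
    rs <- rowSums(tm$P)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    expect_equal(sum(tm$fixation_probs), 1)
    expect_true(all(tm$P >= 0 & tm$P <= 1))
  }
})

test_that("visual entropy matches hand evaluation and its maximum", {
  tm <- function(P, fp, ids = c("A", "B", "C")[seq_along(fp)]) {
    dimnames(P) <- list(ids, ids)
    structure(list(roi_ids = ids, P = P, fixation_probs = fp),
              class = "transition_matrix")
  }
  # deterministic cycle: zero entropy
  P <- rbind(c(0, 1), c(1, 0))
  expect_equal(visual_entropy(tm(P, c(0.5, 0.5), c("A", "B"))), 0)

  # uniform off-diagonal rows over 2 targets: 1 bit
  P <- rbind(c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  expect_equal(visual_entropy(tm(P, rep(1 / 3, 3))), 1)

  # hand-evaluated mixed case: rows (0.9, 0.1), weights (0.5, 0.5, 0)
  h_row <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  P <- rbind(c(0, .9, .1), c(.9, 0, .1), c(0, 0, 0))
  expect_equal(visual_entropy(tm(P, c(0.5, 0.5, 0))), h_row, tolerance = 1e-12)
  expect_equal(round(h_row, 3), 0.469)

  # maximum log2(m-1) reached exactly at uniform off-diagonal rows (m = 3, 4)
  for (m in c(3L, 4L)) {
    ids <- LETTERS[seq_len(m)]
    P <- matrix(1 / (m - 1), m, m); diag(P) <- 0
    fp <- runif(m); fp <- fp / sum(fp)
    expect_equal(visual_entropy(tm(P, fp, ids)), log2(m - 1))
    # any deviation from uniform rows reduces it
    P2 <- P
    P2[1, 2] <- P2[1, 2] + 0.1
    P2[1, 3] <- P2[1, 3] - 0.1
    expect_lt(visual_entropy(tm(P2, fp, ids)), log2(m - 1))
  }
})

test_that("nearest-neighbour index: degenerate, lattice and CSR cases", {
  expect_equal(nearest_neighbour_index(cbind(rep(1, 5), rep(2, 5)), area = 4), 0)

  # square lattice of spacing s over area N s^2: NNI = 2
  g <- expand.grid(x = 1:10, y = 1:10)
  expect_equal(nearest_neighbour_index(g, area = 100), 2)

  expect_error(nearest_neighbour_index(g, area = -1), "area")

  # CSR: single large draw close to 1
  set.seed(500)
  pts <- cbind(runif(10000), runif(10000))
  expect_equal(nearest_neighbour_index(pts, area = 1), 1, tolerance = 0.05)

  # CSR convergence: mean over seeded replicates within 0.05 of 1
  nni <- vapply(1:100, function(k) {
    set.seed(1000 + k)
    p <- cbind(runif(2048), runif(2048))
    nearest_neighbour_index(p, area = 1)
  }, numeric(1))
  expect_equal(mean(nni), 1, tolerance = 0.05)
})

test_that("pupil band power recovers sinusoid power and rejects out-of-band", {
  fs <- 60
  t <- seq(0, 30, by = 1 / fs)
  base <- 2.5

  s <- gaze_stream(t, 0, 0, pupil_radius = rep(base, length(t)),
                   sampling_rate = fs)
  expect_lt(pupil_spectral_power(s), 1e-10)

  a <- 0.3
  s <- gaze_stream(t, 0, 0, pupil_radius = base + a * sin(2 * pi * 4 * t),
                   sampling_rate = fs)
  expect_equal(pupil_spectral_power(s), a^2 / 2, tolerance = 0.05)

  s1 <- gaze_stream(t, 0, 0, pupil_radius = base + a * sin(2 * pi * 1 * t),
                    sampling_rate = fs)
  expect_lt(pupil_spectral_power(s1), 0.01 * a^2 / 2)

  expect_error(pupil_spectral_power(gaze_stream(t, 0, 0, sampling_rate = fs)),
               "pupil")
})

test_that("blink metrics are exact ratios and translation invariant", {
  bl <- function(starts, durs) {
    b <- data.frame(t_start = starts, t_end = starts + durs, duration = durs,
                    partial = logical(length(starts)))
    class(b) <- c("blink_events", "data.frame")
    b
  }
  m <- blink_metrics(bl(seq(1, 29, length.out = 5), rep(0.2, 5)), t_span = 30)
  expect_equal(m$blink_rate, 10)

  m0 <- blink_metrics(bl(numeric(0), numeric(0)), t_span = 10)
  expect_equal(m0$blink_rate, 0)
  expect_equal(m0$percent_closure, 0)

  m1 <- blink_metrics(bl(4, 1), t_span = 10)
  expect_equal(m1$percent_closure, 10)

  # translation invariance
  b <- bl(c(1, 5, 9), c(0.1, 0.2, 0.3))
  b2 <- b; b2$t_start <- b2$t_start + 100; b2$t_end <- b2$t_end + 100
  expect_identical(blink_metrics(b, 12), blink_metrics(b2, 12))
})
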