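# shared fixture builders: everything generated in code, no stored data

# constant-position gaze stream; optional invalid runs given as (start, end) s
make_stream <- function(duration = 1, fs = 100, x = 0, y = 0,
                        invalid = NULL, pupil = NULL) {
  t <- seq(0, duration, by = 1 / fs)
  n <- length(t)
  valid <- rep(TRUE, n)
  if (!is.null(invalid)) {
    for (iv in invalid) valid[t >= iv[1] & t < iv[2]] <- FALSE
  }
  gaze_stream(t, rep_len(x, n), rep_len(y, n),
              pupil_radius = pupil, valid = valid, sampling_rate = fs)
}

# piecewise-stationary stream: dwell at each (x, y) row for `hold` seconds,
# joined by linear ramps of `ramp` seconds
make_steps_stream <- function(points, hold = 0.4, ramp = 0.05, fs = 100) {
  xs <- c(); ys <- c()
  n_hold <- round(hold * fs); n_ramp <- round(ramp * fs)
  for (i in seq_len(nrow(points))) {
    xs <- c(xs, rep(points[i, 1], n_hold))
    ys <- c(ys, rep(points[i, 2], n_hold))
    if (i < nrow(points)) {
      frac <- seq_len(n_ramp) / (n_ramp + 1)
      xs <- c(xs, points[i, 1] + frac * (points[i + 1, 1] - points[i, 1]))
      ys <- c(ys, points[i, 2] + frac * (points[i + 1, 2] - points[i, 2]))
    }
  }
  t <- (seq_along(xs) - 1) / fs
  gaze_stream(t, xs, ys, sampling_rate = fs)
}

# brute-force greedy dispersion-window oracle for fixation detection:
# recomputes the dispersion from scratch at every candidate extension
oracle_fixations <- function(stream, d_max, min_duration) {
  disp <- function(i, j) {
    sqrt((max(stream$x[i:j]) - min(stream$x[i:j]))^2 +
           (max(stream$y[i:j]) - min(stream$y[i:j]))^2)
  }
  runs <- cogniphys:::valid_runs(stream)
  out <- list()
  for (run in runs) {
    lo <- run[1L]; hi <- run[length(run)]
    i <- lo
    while (i <= hi) {
      j <- i
      while (j < hi && disp(i, j + 1L) < d_max) j <- j + 1L
      if (stream$t[j] - stream$t[i] >= min_duration) {
        out[[length(out) + 1L]] <- c(i = i, j = j)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  out
}

# standard three-cluster workload session spec
workload_states <- function(per_state = 200) {
  data.frame(label = c("low", "mid", "high"),
             duration = rep(per_state, 3L))
}

# Monte-Carlo uncertainty oracle: sample inputs, run inference, take the sd
mc_propagate <- function(model, x, sigma, n = 1e5) {
  X <- do.call(cbind, lapply(names(model$inputs), function(nm)
    stats::rnorm(n, x[[nm]], sigma[[nm]])))
  colnames(X) <- names(model$inputs)
  W <- cogniphys:::firing_strengths(model, X)
  S <- rowSums(W)
  ok <- S > 0
  Fv <- cogniphys:::consequent_values(model, X[ok, , drop = FALSE])
  y <- rowSums((W[ok, , drop = FALSE] / S[ok]) * Fv)
  stats::sd(y)
}
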