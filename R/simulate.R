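#' Simulate a gaze stream with known event structure
#'
#' Generates a fixation-saccade-blink renewal process over a set of ROIs:
#' fixation durations are Gaussian (truncated at 50 ms), fixation locations
#' are ROI centres plus small tremor, the next ROI is drawn from a supplied
#' row-stochastic transition table (zero diagonal), saccades move between
#' ROI centres at a constant velocity derived from the requested peak
#' velocity, and blinks arrive as a Poisson process thinned to fall inside
#' fixations only (never overlapping saccades). All randomness flows from the
#' one seed; identical spec and seed give identical output.
#'
#' @param rois A [roi_layout()].
#' @param duration Record length in seconds.
#' @param transition_probs Square row-stochastic matrix with zero diagonal
#'   (rows/cols in ROI order); default uniform over the other ROIs.
#' @param fixation_duration_mean,fixation_duration_sd Seconds.
#' @param saccade_peak_velocity Degrees per second.
#' @param blink_rate Blinks per minute (0 disables blinks).
#' @param blink_duration_mean Seconds.
#' @param pupil_baseline,pupil_noise_sd Pupil radius in mm.
#' @param tremor_sd Within-fixation positional jitter in degrees.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return List with `stream` (a [gaze_stream()]) and `truth`: data frames
#'   `fixations`, `saccades`, `blinks` of generated events.
#' @export
simulate_gaze <- function(rois, duration = 60,
                          transition_probs = NULL,
                          fixation_duration_mean = 0.3,
                          fixation_duration_sd = 0.1,
                          saccade_peak_velocity = 300,
                          blink_rate = 10,
                          blink_duration_mean = 0.15,
                          pupil_baseline = 2.5,
                          pupil_noise_sd = 0.02,
                          tremor_sd = 0.05,
                          sampling_rate = 100,
                          seed = 1L) {
  stopifnot(inherits(rois, "roi_layout"), duration > 0, sampling_rate > 0,
            fixation_duration_mean > 0, blink_rate >= 0,
            blink_duration_mean > 0)
  m <- nrow(rois)
  if (is.null(transition_probs)) {
    transition_probs <- matrix(if (m > 1L) 1 / (m - 1) else 0, m, m)
    diag(transition_probs) <- 0
  }
  transition_probs <- as.matrix(transition_probs)
  stopifnot(nrow(transition_probs) == m, ncol(transition_probs) == m,
            all(abs(diag(transition_probs)) == 0))
  if (m > 1L) stopifnot(all(abs(rowSums(transition_probs) - 1) < 1e-9))
  set.seed(seed)
  cx <- (rois$x_min + rois$x_max) / 2
  cy <- (rois$y_min + rois$y_max) / 2
  dt <- 1 / sampling_rate
  t <- seq(0, duration, by = dt)
  n <- length(t)
  x <- numeric(n); y <- numeric(n)
  fix_log <- list(); sac_log <- list()
  roi <- sample.int(m, 1L)
  i <- 1L
  while (i <= n) {
    dur <- max(0.05, stats::rnorm(1L, fixation_duration_mean,
                                  fixation_duration_sd))
    n_fix <- min(n - i + 1L, max(2L, round(dur * sampling_rate)))
    sel <- i:(i + n_fix - 1L)
    x[sel] <- cx[roi] + stats::rnorm(n_fix, 0, tremor_sd)
    y[sel] <- cy[roi] + stats::rnorm(n_fix, 0, tremor_sd)
    fix_log[[length(fix_log) + 1L]] <- data.frame(
      roi_id = rois$roi_id[roi], t_start = t[sel[1L]], t_end = t[sel[n_fix]])
    i <- i + n_fix
    if (i > n) break
    if (m == 1L) next  # single ROI: fixations only, no saccades
    nxt <- sample.int(m, 1L, prob = transition_probs[roi, ])
    amp <- sqrt((cx[nxt] - cx[roi])^2 + (cy[nxt] - cy[roi])^2)
    sdur <- min(0.08, max(0.03, amp / saccade_peak_velocity))
    n_sac <- min(n - i + 1L, max(1L, round(sdur * sampling_rate)))
    frac <- seq_len(n_sac) / n_sac
    sel <- i:(i + n_sac - 1L)
    x[sel] <- cx[roi] + frac * (cx[nxt] - cx[roi])
    y[sel] <- cy[roi] + frac * (cy[nxt] - cy[roi])
    sac_log[[length(sac_log) + 1L]] <- data.frame(
      t_start = t[sel[1L]], t_end = t[sel[n_sac]], amplitude = amp)
    i <- i + n_sac
    roi <- nxt
  }
  valid <- rep(TRUE, n)
  blink_log <- data.frame(t_start = numeric(0), t_end = numeric(0))
  if (blink_rate > 0) {
    n_blinks <- stats::rpois(1L, blink_rate / 60 * duration)
    if (n_blinks > 0L) {
      cand <- sort(stats::runif(n_blinks, 0, duration))
      sac_iv <- if (length(sac_log)) do.call(rbind, sac_log) else NULL
      for (b in cand) {
        bdur <- max(0.05, stats::rnorm(1L, blink_duration_mean,
                                       blink_duration_mean / 4))
        b_end <- b + bdur
        # thin: drop blinks overlapping a saccade or an earlier blink
        if (!is.null(sac_iv) &&
            any(b < sac_iv$t_end & sac_iv$t_start < b_end)) next
        if (nrow(blink_log) &&
            any(b < blink_log$t_end & blink_log$t_start < b_end)) next
        sel <- t >= b & t < b_end
        if (!any(sel)) next
        valid[sel] <- FALSE
        blink_log <- rbind(blink_log,
                           data.frame(t_start = b, t_end = b_end))
      }
    }
  }
  pupil <- pupil_baseline + stats::rnorm(n, 0, pupil_noise_sd)
  pupil[!valid] <- NA
  stream <- gaze_stream(t, x, y, pupil_radius = pupil, valid = valid,
                        sampling_rate = sampling_rate)
  list(stream = stream,
       truth = list(
         fixations = if (length(fix_log)) do.call(rbind, fix_log) else NULL,
         saccades = if (length(sac_log)) do.call(rbind, sac_log) else NULL,
         blinks = blink_log))
}

#' Simulate an RR-interval series with known spectral content
#'
#' Additive sinusoidal modulation of a constant mean interval:
#' \eqn{RR_i = \overline{RR} + a_{LF}\sin(2\pi f_{LF} t_i)
#'       + a_{HF}\sin(2\pi f_{HF} t_i) + \epsilon_i},
#' with beat times accumulated from the intervals themselves. This gives
#' closed-form ground-truth band powers (each tone contributes
#' \eqn{a^2/2}). Ectopic beats are injected by halving intervals at a given
#' per-beat probability.
#'
#' @param duration Record length in seconds.
#' @param mean_rr Mean interval in ms (within 300--2000).
#' @param lf_amp,hf_amp Modulation amplitudes in ms.
#' @param lf_freq,hf_freq Modulation frequencies in Hz; must lie in the LF
#'   (0.04--0.15) and HF (0.15--0.4) bands respectively.
#' @param jitter_sd Beat-to-beat Gaussian noise sd in ms.
#' @param ectopic_rate Per-beat probability of an ectopic (halved) interval.
#' @param seed Integer seed.
#' @return List with `rr` (an [rr_series()]), `truth` (band powers in ms^2
#'   and the ectopic count).
#' @export
simulate_rr <- function(duration = 300, mean_rr = 800,
                        lf_amp = 25, hf_amp = 25,
                        lf_freq = 0.1, hf_freq = 0.3,
                        jitter_sd = 5, ectopic_rate = 0,
                        seed = 1L) {
  stopifnot(mean_rr > 300, mean_rr < 2000,
            lf_freq >= 0.04, lf_freq <= 0.15,
            hf_freq >= 0.15, hf_freq <= 0.4)
  set.seed(seed)
  rr <- numeric(0)
  t_i <- 0
  n_ect <- 0L
  while (t_i < duration) {
    val <- mean_rr + lf_amp * sin(2 * pi * lf_freq * t_i) +
      hf_amp * sin(2 * pi * hf_freq * t_i) + stats::rnorm(1L, 0, jitter_sd)
    val <- max(val, 250)
    if (ectopic_rate > 0 && stats::runif(1L) < ectopic_rate) {
      val <- val / 2
      n_ect <- n_ect + 1L
    }
    rr <- c(rr, val)
    t_i <- t_i + val / 1000
  }
  list(rr = rr_series(rr),
       truth = list(lf_power = lf_amp^2 / 2, hf_power = hf_amp^2 / 2,
                    ectopic_count = n_ect))
}

#' Simulate a respiration volume trace
#'
#' Quasi-sinusoidal lung-volume signal of amplitude `tv / 2` (so the
#' peak-to-trough tidal volume is `tv`), with optional linear drift and
#' additive Gaussian noise.
#'
#' @param br Breathing rate in breaths/min, in (4, 60).
#' @param tv Tidal volume (peak-to-trough) in mL.
#' @param duration Seconds.
#' @param drift Linear drift in mL/s.
#' @param noise_sd Additive noise sd in mL.
#' @param sampling_rate Hz.
#' @param seed Integer seed.
#' @return A [respiration_signal()].
#' @export
simulate_respiration <- function(br = 15, tv = 500, duration = 60,
                                 drift = 0, noise_sd = 0,
                                 sampling_rate = 25, seed = 1L) {
  stopifnot(br > 4, br < 60, tv > 0, duration > 0)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / sampling_rate)
  v <- tv / 2 * sin(2 * pi * br / 60 * t) + drift * t +
    stats::rnorm(length(t), 0, noise_sd)
  respiration_signal(t, v)
}

#' Simulate a degraded copy of a reference series
#'
#' Produces a reference/measured pair from a ground-truth series: the
#' measured channel is the truth delayed by `latency`, offset by `bias`, with
#' added Gaussian noise — the substrate for validity characterisation
#' against a clinically validated device.
#'
#' @param truth Data frame `(t, value)` or numeric vector.
#' @param bias Constant offset added to the measured channel.
#' @param noise_sd Gaussian noise sd.
#' @param latency Measurement delay in seconds (vector input assumes unit
#'   spacing).
#' @param seed Integer seed.
#' @return A [paired_series()].
#' @export
simulate_sensor_pair <- function(truth, bias = 0, noise_sd = 0, latency = 0,
                                 seed = 1L) {
  set.seed(seed)
  if (is.numeric(truth)) truth <- data.frame(t = seq_along(truth) - 1,
                                             value = truth)
  stopifnot(nrow(truth) >= 2L)
  delayed <- stats::approx(truth$t, truth$value, xout = truth$t - latency,
                           rule = 2)$y
  measured <- delayed + bias + stats::rnorm(nrow(truth), 0, noise_sd)
  paired_series(data.frame(t = truth$t, value = truth$value),
                data.frame(t = truth$t, value = measured), max_lag = Inf)
}

#' Simulate a labelled workload session
#'
#' Draws per-epoch heart-rate and breathing-rate features around
#' state-specific cluster centres (defaults: the low/medium/high mental
#' workload centres HR 63.2/64.9/68.3 and BR 11.5/14.6/15.3 min^-1) with
#' Gaussian within-state scatter, one row per second of each state. The
#' exported labels support calibration round trips.
#'
#' @param states Data frame `(label, duration)` with labels among
#'   `"low", "mid", "high"` and durations in seconds.
#' @param hr_means,br_means Named per-state means (min^-1).
#' @param hr_sd,br_sd Within-state standard deviations (min^-1). The state
#'   means are cluster centres identified from a participant's session, so
#'   the emulated within-cluster spread must sit below the between-centre
#'   gaps for the clusters to have been identifiable at all; the defaults
#'   are about half the smallest centre gap of each input.
#' @param seed Integer seed.
#' @return Data frame `(t, HR, BR, label)`.
#' @export
simulate_workload_session <- function(states,
                                      hr_means = c(low = 63.2, mid = 64.9, high = 68.3),
                                      br_means = c(low = 11.5, mid = 14.6, high = 15.3),
                                      hr_sd = 0.8, br_sd = 0.35,
                                      seed = 1L) {
  stopifnot(is.data.frame(states), all(c("label", "duration") %in% names(states)),
            all(states$duration >= 0),
            all(states$label %in% names(hr_means)))
  set.seed(seed)
  out <- list()
  t0 <- 0
  for (r in seq_len(nrow(states))) {
    n <- floor(states$duration[r])
    if (n > 0L) {
      lab <- states$label[r]
      out[[length(out) + 1L]] <- data.frame(
        t = t0 + seq_len(n) - 1,
        HR = stats::rnorm(n, hr_means[[lab]], hr_sd),
        BR = stats::rnorm(n, br_means[[lab]], br_sd),
        label = lab)
    }
    t0 <- t0 + states$duration[r]
  }
  if (!length(out)) {
    return(data.frame(t = numeric(0), HR = numeric(0), BR = numeric(0),
                      label = character(0)))
  }
  do.call(rbind, out)
}
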