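#' Construct a respiration signal
#'
#' A strain-gauge-proportional lung volume trace.
#'
#' @param t Seconds, strictly increasing (assumed uniformly sampled).
#' @param volume Volume in mL.
#' @return Object of class `respiration_signal`: data frame with `t`,
#'   `volume` and a `sampling_rate` attribute.
#' @export
respiration_signal <- function(t, volume) {
  if (length(t) < 2L) stop("need at least 2 samples")
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  out <- data.frame(t = as.numeric(t), volume = as.numeric(volume))
  attr(out, "sampling_rate") <- 1 / stats::median(diff(t))
  class(out) <- c("respiration_signal", "data.frame")
  out
}

#' Respiratory rate, tidal volume and minute ventilation
#'
#' Respiratory cycles are detected as alternating peaks and troughs of the
#' 1 Hz low-pass-filtered volume trace (zero crossings of its derivative,
#' minimum cycle spacing 1 s, since physiological breathing rates stay below
#' 60/min). Per-cycle tidal volume is the peak-to-trough difference
#' \eqn{TV_i = V_{peak,i} - V_{trough,i}}; breathing rate is breaths per
#' minute over the record; minute ventilation is
#' \eqn{MV = BR \times \overline{TV}} converted to L/min.
#'
#' @param resp A [respiration_signal()] with at least 2 full cycles.
#' @return Object of class `resp_summary`: `br` (breaths/min), `tv_mean`
#'   (mL), `mv` (L/min) and a `cycles` data frame of `(t_peak, t_trough, tv)`.
#' @export
respiration_metrics <- function(resp) {
  stopifnot(inherits(resp, "respiration_signal"))
  fs <- attr(resp, "sampling_rate")
  v <- resp$volume
  if (fs > 2.5) v <- butterworth_chain(v, fs, lowpass_hz = 1, order = 2)
  if (diff(range(v)) <= 1e-9 * (abs(mean(v)) + 1)) stop("no cycles detected")
  dv <- diff(v)
  s <- sign(dv)
  # derivative zero crossings: +/- -> peak, -/+ -> trough
  idx <- which(s[-1L] != s[-length(s)] & s[-length(s)] != 0) + 1L
  kind <- ifelse(s[idx - 1L] > 0, "peak", "trough")
  if (length(idx) == 0L) stop("no cycles detected")
  # enforce minimum 1 s spacing between same-type extrema: keep the more
  # extreme of two rivals
  keep <- rep(TRUE, length(idx))
  last_kept <- c(peak = NA_integer_, trough = NA_integer_)  # positions in idx
  for (k in seq_along(idx)) {
    prev <- last_kept[[kind[k]]]
    if (!is.na(prev) && resp$t[idx[k]] - resp$t[idx[prev]] < 1) {
      better <- if (kind[k] == "peak") v[idx[k]] > v[idx[prev]] else
        v[idx[k]] < v[idx[prev]]
      if (better) {
        keep[prev] <- FALSE
        last_kept[[kind[k]]] <- k
      } else {
        keep[k] <- FALSE
      }
    } else {
      last_kept[[kind[k]]] <- k
    }
  }
  idx <- idx[keep]; kind <- kind[keep]
  peaks <- idx[kind == "peak"]; troughs <- idx[kind == "trough"]
  if (length(peaks) < 2L || length(troughs) < 1L) stop("no cycles detected")
  # pair each peak with the nearest following trough
  cycles <- data.frame(t_peak = numeric(0), t_trough = numeric(0), tv = numeric(0))
  for (p in peaks) {
    tr <- troughs[troughs > p]
    if (!length(tr)) next
    tr <- tr[1L]
    cycles <- rbind(cycles, data.frame(t_peak = resp$t[p], t_trough = resp$t[tr],
                                       tv = v[p] - v[tr]))
  }
  if (nrow(cycles) < 2L) stop("no cycles detected")
  span <- resp$t[nrow(resp)] - resp$t[1L]
  br <- length(peaks) / span * 60
  tv_mean <- mean(cycles$tv)
  out <- list(br = br, tv_mean = tv_mean, mv = br * tv_mean / 1000,
              cycles = cycles)
  class(out) <- "resp_summary"
  out
}

#' @export
print.resp_summary <- function(x, ...) {
  cat(sprintf("BR %.2f breaths/min | TV %.0f mL | MV %.2f L/min (%d cycles)\n",
              x$br, x$tv_mean, x$mv, nrow(x$cycles)))
  invisible(x)
}

#' Zero-phase Butterworth conditioning chain
#'
#' Applies the requested cascade of order-`order` Butterworth sections
#' (12 dB/octave per section at the default order 2) forward-backward
#' (zero phase): optional high-pass, low-pass and notch (band-stop around
#' `notch_hz`). This is the standard conditioning used for physiological
#' signals, e.g. a 0.1 Hz high-pass, 30 Hz low-pass and 50 Hz mains notch
#' for EEG-like traces, or a plain low-pass for cardiorespiratory data.
#' Forward-backward application squares the magnitude response, so the
#' effective roll-off is twice the design order.
#'
#' @param x Uniformly sampled numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lowpass_hz,highpass_hz,notch_hz Cutoff/centre frequencies in Hz;
#'   `NULL` skips the stage. All must lie below the Nyquist frequency.
#' @param order Butterworth section order (default 2).
#' @param notch_halfwidth Half-width of the notch stop band in Hz.
#' @return The filtered signal.
#' @export
butterworth_chain <- function(x, fs, lowpass_hz = NULL, highpass_hz = NULL,
                              notch_hz = NULL, order = 2, notch_halfwidth = 2) {
  nyq <- fs / 2
  for (f in c(lowpass_hz, highpass_hz, notch_hz)) {
    if (!is.null(f) && f >= nyq) stop("cutoff at or above Nyquist frequency")
  }
  y <- as.numeric(x)
  n <- length(y)
  # odd-reflection edge padding before forward-backward filtering, scaled to
  # the slowest stage, so start-up transients stay out of the record
  f_slow <- min(c(lowpass_hz, highpass_hz, notch_hz))
  pad <- min(n - 1L, max(24L * order, ceiling(5 * fs / f_slow)))
  apply_zero_phase <- function(flt, y) {
    head_pad <- 2 * y[1L] - y[(pad + 1L):2L]
    tail_pad <- 2 * y[n] - y[(n - 1L):(n - pad)]
    out <- signal::filtfilt(flt, c(head_pad, y, tail_pad))
    out[(pad + 1L):(pad + n)]
  }
  if (!is.null(highpass_hz)) {
    y <- apply_zero_phase(signal::butter(order, highpass_hz / nyq, type = "high"), y)
  }
  if (!is.null(lowpass_hz)) {
    y <- apply_zero_phase(signal::butter(order, lowpass_hz / nyq, type = "low"), y)
  }
  if (!is.null(notch_hz)) {
    band <- c(max(notch_hz - notch_halfwidth, 1e-6), notch_hz + notch_halfwidth)
    y <- apply_zero_phase(signal::butter(order, band / nyq, type = "stop"), y)
  }
  y
}
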