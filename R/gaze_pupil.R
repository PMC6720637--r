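#' Pupil dilation spectral power
#'
#' Integral of the pupil-radius power spectral density over a frequency band
#' (default 2--6 Hz), a pupillometric arousal/workload index. The PSD is a
#' Welch periodogram (Hann window, segments of at most 4 s, 50% overlap);
#' gaps from blinks or pupil loss are linearly interpolated before
#' transforming.
#'
#' @param stream A [gaze_stream()] with a pupil channel, sampled above 12 Hz
#'   (Nyquist for the 6 Hz band edge).
#' @param band Two-element frequency band in Hz.
#' @return Band power in units of radius squared (mm^2); nonnegative.
#' @export
pupil_spectral_power <- function(stream, band = c(2, 6)) {
  stopifnot(is_gaze_stream(stream))
  fs <- attr(stream, "sampling_rate")
  if (all(is.na(stream$pupil_radius))) stop("missing pupil channel")
  if (fs <= 2 * max(band)) stop("sampling rate below Nyquist for the requested band")
  r <- stream$pupil_radius
  r[!stream$valid] <- NA
  ok <- which(!is.na(r))
  if (length(ok) < 8L) stop("too few valid pupil samples")
  r <- stats::approx(stream$t[ok], r[ok], xout = stream$t, rule = 2)$y
  seg <- min(round(4 * fs), length(r))
  sp <- welch_psd(r, fs, seg_len = seg)
  band_power(sp$freq, sp$psd, band[1L], band[2L])
}

#' Blink rate and percentage eye closure
#'
#' Blink rate is the blink count per minute over the observation span;
#' percentage closure (PERCLOS-style) is the summed closure time as a
#' percentage of the span. Both are invariant under time translation.
#'
#' @param blinks A `blink_events` frame, all lying within the span.
#' @param t_span Observation span in seconds.
#' @return List with `blink_rate` (blinks/min) and `percent_closure` (0-100).
#' @export
blink_metrics <- function(blinks, t_span) {
  stopifnot(t_span > 0)
  list(blink_rate = nrow(blinks) / t_span * 60,
       percent_closure = 100 * sum(blinks$duration) / t_span)
}
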