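#' Detect blinks from the validity channel
#'
#' Blinks are maximal runs of invalid samples (eyelid closure or pupil loss)
#' no longer than `max_gap`; longer invalid runs are classified as tracking
#' loss and not reported. A run is flagged `partial` when the pupil channel is
#' present but never fully lost during the run.
#'
#' @param stream A [gaze_stream()].
#' @param max_gap Longest invalid run (seconds) still counted as a blink.
#' @return A data frame of class `blink_events` with columns `t_start`,
#'   `t_end`, `duration`, `partial`, ordered and non-overlapping.
#' @export
detect_blinks <- function(stream, max_gap = 0.5) {
  stopifnot(is_gaze_stream(stream))
  if (nrow(stream) == 0L) stop("no samples")
  inv <- !stream$valid
  r <- rle(inv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0), partial = logical(0))
  dt <- 1 / attr(stream, "sampling_rate")
  t_last <- stream$t[nrow(stream)]
  for (k in keep) {
    i <- starts[k]; j <- ends[k]
    # run duration includes the sample period of the last closed sample,
    # clamped so the event stays inside the stream's time span
    t_end <- min(stream$t[j] + dt, t_last)
    dur <- t_end - stream$t[i]
    if (dur > max_gap) next  # tracking loss, not a blink
    partial <- !all(is.na(stream$pupil_radius[i:j])) &&
      any(!is.na(stream$pupil_radius[i:j]))
    out <- rbind(out, data.frame(t_start = stream$t[i], t_end = t_end,
                                 duration = dur, partial = partial))
  }
  class(out) <- c("blink_events", "data.frame")
  out
}

# dispersion of a set of samples: diagonal of the bounding box in degrees
dispersion <- function(x, y) {
  sqrt((max(x) - min(x))^2 + (max(y) - min(y))^2)
}

#' Detect fixations by dispersion-threshold identification (I-DT)
#'
#' A fixation is a maximal window of consecutive valid samples whose
#' dispersion, the diagonal of the bounding box
#' \eqn{D=\sqrt{(x_{max}-x_{min})^2+(y_{max}-y_{min})^2}}, stays below
#' `d_max` and whose duration reaches `min_duration`. Invalid (blink) samples
#' split the stream; fixations never span them.
#'
#' @param stream A [gaze_stream()] with blink samples already flagged invalid.
#' @param d_max Dispersion threshold in degrees.
#' @param min_duration Minimum fixation duration in seconds.
#' @return A data frame of class `fixation_events` with columns `t_start`,
#'   `t_end`, `duration`, `centroid_x`, `centroid_y`, `dispersion`.
#' @export
detect_fixations <- function(stream, d_max = 1.0, min_duration = 0.1) {
  stopifnot(is_gaze_stream(stream), d_max > 0, min_duration > 0)
  out <- list()
  for (run in valid_runs(stream)) {
    t <- stream$t[run]; x <- stream$x[run]; y <- stream$y[run]
    n <- length(run)
    i <- 1L
    while (i <= n) {
      # grow a window from i while dispersion stays below d_max
      j <- i
      xmin <- x[i]; xmax <- x[i]; ymin <- y[i]; ymax <- y[i]
      while (j < n) {
        nxmin <- min(xmin, x[j + 1L]); nxmax <- max(xmax, x[j + 1L])
        nymin <- min(ymin, y[j + 1L]); nymax <- max(ymax, y[j + 1L])
        if (sqrt((nxmax - nxmin)^2 + (nymax - nymin)^2) >= d_max) break
        j <- j + 1L
        xmin <- nxmin; xmax <- nxmax; ymin <- nymin; ymax <- nymax
      }
      if (t[j] - t[i] >= min_duration) {
        out[[length(out) + 1L]] <- data.frame(
          t_start = t[i], t_end = t[j], duration = t[j] - t[i],
          centroid_x = mean(x[i:j]), centroid_y = mean(y[i:j]),
          dispersion = sqrt((xmax - xmin)^2 + (ymax - ymin)^2))
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(t_start = numeric(0), t_end = numeric(0), duration = numeric(0),
               centroid_x = numeric(0), centroid_y = numeric(0),
               dispersion = numeric(0))
  class(out) <- c("fixation_events", "data.frame")
  out
}

#' Time to first fixation
#'
#' Latency from a reference instant `t0` (stimulus onset) to the onset of the
#' first fixation.
#'
#' @param fixations A `fixation_events` frame, ordered in time.
#' @param t0 Reference time in seconds.
#' @return Seconds from `t0` to the first fixation onset.
#' @export
time_to_first_fixation <- function(fixations, t0 = 0) {
  if (nrow(fixations) == 0L) stop("no fixations")
  fixations$t_start[1L] - t0
}

#' Detect saccades by velocity threshold
#'
#' Angular velocity is estimated by central finite differences of gaze
#' position, smoothed with a 3-sample median filter. A saccade is a maximal
#' run of samples with velocity at or above `v_threshold` whose duration lies
#' within `dur_bounds` (saccades physiologically last about 30--80 ms);
#' faster-than-threshold epochs outside those bounds (e.g. smooth pursuit)
#' are discarded.
#'
#' @param stream A [gaze_stream()], regularly sampled at 60 Hz or more
#'   (velocity differentiation is unreliable below; a warning is issued).
#' @param v_threshold Velocity threshold in deg/s.
#' @param dur_bounds Admissible saccade duration range in seconds.
#' @return A data frame of class `saccade_events` with columns `t_start`,
#'   `t_end`, `duration`, `amplitude`, `mean_velocity`, `peak_velocity`,
#'   and a `low_confidence` attribute when the sampling rate is below 60 Hz.
#' @export
detect_saccades <- function(stream, v_threshold = 30,
                            dur_bounds = c(0.03, 0.08)) {
  stopifnot(is_gaze_stream(stream))
  fs <- attr(stream, "sampling_rate")
  low_conf <- fs < 60
  if (low_conf) warning("sampling rate below 60 Hz: saccade velocities are low-confidence")
  out <- list()
  for (run in valid_runs(stream)) {
    if (length(run) < 3L) next
    t <- stream$t[run]; x <- stream$x[run]; y <- stream$y[run]
    n <- length(run)
    # central differences; one-sided at run edges
    vx <- c(diff(x[1:2]) / diff(t[1:2]),
            (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
            diff(x[(n - 1):n]) / diff(t[(n - 1):n]))
    vy <- c(diff(y[1:2]) / diff(t[1:2]),
            (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
            diff(y[(n - 1):n]) / diff(t[(n - 1):n]))
    v <- sqrt(vx^2 + vy^2)
    v <- stats::runmed(v, 3, endrule = "keep")
    r <- rle(v >= v_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      dur <- t[j] - t[i]
      if (dur < dur_bounds[1L] || dur > dur_bounds[2L]) next
      out[[length(out) + 1L]] <- data.frame(
        t_start = t[i], t_end = t[j], duration = dur,
        amplitude = sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2),
        mean_velocity = mean(v[i:j]), peak_velocity = max(v[i:j]))
    }
  }
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(t_start = numeric(0), t_end = numeric(0), duration = numeric(0),
               amplitude = numeric(0), mean_velocity = numeric(0),
               peak_velocity = numeric(0))
  attr(out, "low_confidence") <- low_conf
  class(out) <- c("saccade_events", "data.frame")
  out
}

#' Explore/exploit ratio
#'
#' The ratio of total oculomotor events (saccades plus all fixations) to the
#' number of long fixations; an index of visual search randomness, higher
#' when scanning dominates over sustained inspection.
#'
#' @param fixations A `fixation_events` frame.
#' @param saccades A `saccade_events` frame.
#' @param long_fix_threshold Duration (seconds) above which a fixation counts
#'   as "long".
#' @return Dimensionless ratio, at least 1 whenever a long fixation exists.
#' @export
explore_exploit_ratio <- function(fixations, saccades, long_fix_threshold = 0.5) {
  stopifnot(long_fix_threshold > 0)
  n_long <- sum(fixations$duration >= long_fix_threshold)
  if (n_long == 0L) stop("undefined ratio: no long fixations")
  (nrow(saccades) + nrow(fixations)) / n_long
}
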