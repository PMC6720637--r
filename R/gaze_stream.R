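#' Construct a gaze stream
#'
#' A gaze stream is the raw input to all eye-activity metrics: a regularly
#' sampled sequence of gaze angles (degrees, screen-referenced, x rightward,
#' y upward) with an optional pupil-radius channel and a per-sample validity
#' flag that is `FALSE` during blinks and tracking loss.
#'
#' @param t Sample timestamps in seconds, strictly increasing.
#' @param x,y Gaze angle in degrees.
#' @param pupil_radius Pupil radius in mm, or `NULL` if the sensor does not
#'   report it. `NA` values are allowed (momentary pupil loss).
#' @param valid Logical vector, one flag per sample; `FALSE` marks samples
#'   recorded during blinks or tracking loss.
#' @param sampling_rate Declared sampling rate in Hz. Must be consistent with
#'   the median inter-sample gap within 10%.
#'
#' @return A `gaze_stream`: a data frame with columns `t`, `x`, `y`,
#'   `pupil_radius`, `valid` and a `sampling_rate` attribute.
#' @export
#' @examples
#' s <- gaze_stream(t = seq(0, 1, by = 0.01), x = 0, y = 0, sampling_rate = 100)
#' nrow(s)
gaze_stream <- function(t, x, y, pupil_radius = NULL, valid = TRUE,
                        sampling_rate = NULL) {
  if (length(t) == 0L) stop("no samples")
  n <- length(t)
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  valid <- rep_len(as.logical(valid), n)
  if (is.null(pupil_radius)) {
    pupil_radius <- rep(NA_real_, n)
  } else {
    pupil_radius <- rep_len(as.numeric(pupil_radius), n)
  }
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(t))
  }
  if (sampling_rate <= 0) stop("sampling_rate must be > 0")
  if (n > 1L) {
    gap <- stats::median(diff(t))
    if (abs(gap - 1 / sampling_rate) > 0.1 / sampling_rate) {
      stop("declared sampling_rate inconsistent with timestamps (>10%)")
    }
  }
  out <- data.frame(t = as.numeric(t), x = x, y = y,
                    pupil_radius = pupil_radius, valid = valid)
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("gaze_stream", "data.frame")
  out
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("<gaze_stream> %d samples @ %.6g Hz, %.6g s span, %.1f%% valid\n",
              nrow(x), attr(x, "sampling_rate"),
              x$t[nrow(x)] - x$t[1L], 100 * mean(x$valid)))
  invisible(x)
}

#' @rdname gaze_stream
#' @param stream An object to test or coerce.
#' @export
is_gaze_stream <- function(stream) inherits(stream, "gaze_stream")

# split a stream into maximal runs of valid samples (row-index lists)
valid_runs <- function(stream) {
  r <- rle(stream$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) starts[k]:ends[k])
}
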