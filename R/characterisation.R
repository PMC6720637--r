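#' Fixation cluster for eye-tracker characterisation
#'
#' Gaze samples collected while the subject fixates one known target, the
#' unit of static accuracy/precision characterisation. Angular distances are
#' Euclidean in (x, y) gaze-angle degrees — a small-angle approximation of
#' the great-circle distance, in error by under 1% for angles below about
#' 20 degrees.
#'
#' @param x,y Sample gaze angles in degrees (at least 2 samples).
#' @param target_x,target_y True target location in degrees.
#' @return Object of class `fixation_cluster`.
#' @export
fixation_cluster <- function(x, y, target_x, target_y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 target = c(x = target_x, y = target_y)),
            class = "fixation_cluster")
}

#' Gaze precision (RMS of sample scatter)
#'
#' Root-mean-square angular distance of the cluster samples from the cluster
#' mean location, \eqn{\theta_{RMS}=\sqrt{(\theta_1^2+\dots+\theta_n^2)/n}}.
#' Measuring from the cluster mean makes precision independent of accuracy
#' and invariant under rigid motion of the cluster.
#'
#' @param cluster A [fixation_cluster()].
#' @return Precision in degrees.
#' @export
gaze_precision <- function(cluster) {
  stopifnot(inherits(cluster, "fixation_cluster"))
  dx <- cluster$x - mean(cluster$x)
  dy <- cluster$y - mean(cluster$y)
  sqrt(mean(dx^2 + dy^2))
}

#' Gaze accuracy (mean offset from the target)
#'
#' Angular distance between the cluster mean location and the true target
#' location. The magnitude is returned; the signed x/y components are
#' available as the `components` attribute.
#'
#' @param cluster A [fixation_cluster()].
#' @return Accuracy in degrees (magnitude), with attribute `components`.
#' @export
gaze_accuracy <- function(cluster) {
  stopifnot(inherits(cluster, "fixation_cluster"))
  dx <- mean(cluster$x) - cluster$target[["x"]]
  dy <- mean(cluster$y) - cluster$target[["y"]]
  structure(sqrt(dx^2 + dy^2), components = c(x = dx, y = dy))
}

#' Two-sigma dynamic accuracy from a lognormal error fit
#'
#' Dynamic (target-tracking) angular errors are right-skewed; they are
#' summarised by fitting a lognormal distribution by maximum likelihood and
#' reporting \eqn{\exp(\hat\mu + 2\hat\sigma)}, the value below which
#' approximately 95% of the fitted error mass lies.
#'
#' @param errors Positive angular errors in degrees, at least 20 of them.
#' @return The 2-sigma accuracy bound in degrees.
#' @export
two_sigma_dynamic_accuracy <- function(errors) {
  bad <- which(!(errors > 0))
  if (length(bad)) {
    stop(sprintf("non-positive errors at indices: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  if (length(errors) < 20L) stop("need at least 20 errors for a stable fit")
  if (stats::sd(log(errors)) < .Machine$double.eps^0.5) {
    return(errors[1L])  # degenerate cluster: sigma-hat = 0
  }
  fit <- MASS::fitdistr(errors, "lognormal")
  unname(exp(fit$estimate[["meanlog"]] + 2 * fit$estimate[["sdlog"]]))
}

#' Field-of-view uncertainty
#'
#' First-order uncertainty of a field-of-view angle estimated from an object
#' of known size `l` at distance `d`:
#' \deqn{\sigma_{FOV} = \frac{\sqrt{\sigma_l^2 + (l/d)^2\sigma_d^2 - 2(l/d)\sigma_{ld}}}
#'       {d\,[1 + (l/2d)^2]}}
#' The size-distance covariance `sigma_ld` is conventionally set to zero for
#' a conservative estimate.
#'
#' @param l Object dimension (length units).
#' @param d Object-to-camera distance, positive (same units).
#' @param sigma_l,sigma_d 1-sigma uncertainties of `l` and `d`.
#' @param sigma_ld Covariance of the size and distance measurements.
#' @return FOV uncertainty (radians per unit geometry of the formula).
#' @export
fov_uncertainty <- function(l, d, sigma_l, sigma_d, sigma_ld = 0) {
  stopifnot(d > 0, sigma_l >= 0, sigma_d >= 0)
  radicand <- sigma_l^2 + (l / d)^2 * sigma_d^2 - 2 * (l / d) * sigma_ld
  if (radicand < 0) stop("negative radicand: sigma_ld too large for these sigmas")
  sqrt(radicand) / (d * (1 + (l / (2 * d))^2))
}

#' Blink-rate detection error
#'
#' Fraction of blink events the sensor mis-handles: (false positives + false
#' negatives) over the true blink count, the latter typically obtained by
#' manual counting from recorded video.
#'
#' @param false_pos,false_neg Event counts.
#' @param total_blinks True blink count, positive.
#' @return Error fraction (can exceed 1 when spurious detections dominate).
#' @export
blink_rate_error <- function(false_pos, false_neg, total_blinks) {
  if (total_blinks <= 0) stop("total_blinks must be positive")
  (false_pos + false_neg) / total_blinks
}

#' Paired reference/measured sensor series
#'
#' Aligns a test-device stream against a clinically validated reference by a
#' nearest-timestamp join with a maximum admissible lag; unmatched samples
#' are dropped and counted.
#'
#' @param reference Data frame `(t, value)` from the reference device, or a
#'   numeric vector already aligned with `measured`.
#' @param measured Data frame `(t, value)` from the test device, or a
#'   numeric vector.
#' @param max_lag Maximum timestamp mismatch in seconds for the join.
#' @return Object of class `paired_series`: data frame with `t`, `reference`,
#'   `measured`; attributes `alignment` and `n_dropped`.
#' @export
paired_series <- function(reference, measured, max_lag = 0.5) {
  if (is.numeric(reference) && is.numeric(measured)) {
    stopifnot(length(reference) == length(measured), length(reference) >= 2L)
    out <- data.frame(t = seq_along(reference) - 1, reference = reference,
                      measured = measured)
    attr(out, "alignment") <- "index"
    attr(out, "n_dropped") <- 0L
  } else {
    stopifnot(is.data.frame(reference), is.data.frame(measured))
    idx <- vapply(reference$t, function(tt) {
      j <- which.min(abs(measured$t - tt))
      if (abs(measured$t[j] - tt) <= max_lag) j else NA_integer_
    }, integer(1))
    ok <- !is.na(idx)
    if (sum(ok) < 2L) stop("fewer than 2 aligned samples")
    out <- data.frame(t = reference$t[ok], reference = reference$value[ok],
                      measured = measured$value[idx[ok]])
    attr(out, "alignment") <- sprintf("nearest-timestamp join, max lag %g s", max_lag)
    attr(out, "n_dropped") <- sum(!ok)
  }
  class(out) <- c("paired_series", "data.frame")
  out
}

#' Validity of a test sensor against a reference
#'
#' Root-mean-square error
#' \eqn{\sqrt{\frac1n\sum_i (x_i^{ref}-x_i^{meas})^2}} and the
#' product-moment correlation coefficient between the aligned series.
#'
#' @param pair A [paired_series()].
#' @return List with `rms_error` (reference units) and `cc` (in \[-1, 1\];
#'   `NA` with a `cc_reason` attribute when either series has zero variance).
#' @export
validity <- function(pair) {
  stopifnot(inherits(pair, "paired_series"), nrow(pair) >= 2L)
  rms <- sqrt(mean((pair$reference - pair$measured)^2))
  if (stats::sd(pair$reference) == 0 || stats::sd(pair$measured) == 0) {
    out <- list(rms_error = rms, cc = NA_real_)
    attr(out, "cc_reason") <- "zero variance in one series"
    return(out)
  }
  list(rms_error = rms, cc = stats::cor(pair$reference, pair$measured))
}

#' Full characterisation report
#'
#' Convenience aggregation of the sensor performance statistics into one
#' record: static precision/accuracy over fixation clusters, the dynamic
#' two-sigma accuracy, blink-rate error, FOV uncertainty and validity against
#' a reference series. Any component may be omitted.
#'
#' @param clusters List of [fixation_cluster()] objects.
#' @param dynamic_errors Positive dynamic angular errors, or `NULL`.
#' @param pair A [paired_series()], or `NULL`.
#' @param blink_counts List `(false_pos, false_neg, total_blinks)`, or `NULL`.
#' @param fov List of [fov_uncertainty()] arguments, or `NULL`.
#' @return Object of class `characterisation_report` (a named list).
#' @export
characterisation_report <- function(clusters = list(), dynamic_errors = NULL,
                                    pair = NULL, blink_counts = NULL,
                                    fov = NULL) {
  out <- list(
    precision_rms = if (length(clusters))
      mean(vapply(clusters, gaze_precision, numeric(1))) else NA_real_,
    accuracy_mean = if (length(clusters))
      mean(vapply(clusters, function(cl) as.numeric(gaze_accuracy(cl)),
                  numeric(1))) else NA_real_,
    two_sigma_accuracy = if (!is.null(dynamic_errors))
      two_sigma_dynamic_accuracy(dynamic_errors) else NA_real_,
    rms_error = NA_real_, cc = NA_real_,
    blr_error = if (!is.null(blink_counts))
      do.call(blink_rate_error, blink_counts) else NA_real_,
    fov_sigma = if (!is.null(fov)) do.call(fov_uncertainty, fov) else NA_real_)
  if (!is.null(pair)) {
    v <- validity(pair)
    out$rms_error <- v$rms_error
    out$cc <- v$cc
  }
  class(out) <- "characterisation_report"
  out
}

#' @export
print.characterisation_report <- function(x, ...) {
  cat("<characterisation_report>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm,
                                   ifelse(is.na(x[[nm]]), "-", format(x[[nm]]))))
  invisible(x)
}
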