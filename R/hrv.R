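#' Construct an RR-interval series
#'
#' Inter-beat (R-to-R) intervals in milliseconds. Beat onset times (seconds,
#' cumulative) are derived and carried alongside for spectral analysis of the
#' tachogram.
#'
#' @param rr Inter-beat intervals in ms, all positive.
#' @return Object of class `rr_series`: list with `rr` (ms) and `t_onset`
#'   (s, cumulative beat times).
#' @export
#' @examples
#' rr <- rr_series(c(800, 810, 795, 805))
#' rr$t_onset
rr_series <- function(rr) {
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop("empty RR series")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("RR intervals must be positive")
  structure(list(rr = rr, t_onset = cumsum(rr) / 1000), class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals, mean %.1f ms, span %.1f s\n",
              length(x$rr), mean(x$rr), x$t_onset[length(x$t_onset)]))
  invisible(x)
}

#' Remove abnormal beats from an RR series
#'
#' Produces a normal-to-normal (NN) series by rejecting intervals outside
#' physiological bounds or differing from the median of their 5 nearest
#' neighbouring intervals by more than `max_rel_jump` (relative). A warning
#' is issued when more than 20% of beats are rejected.
#'
#' @param rr An [rr_series()].
#' @param bounds Physiological sanity bounds in ms.
#' @param max_rel_jump Maximum tolerated relative deviation from the local
#'   neighbour median.
#' @return Object of class `nn_series`: list with `nn` (ms), `t_onset` (s,
#'   onset times of the retained beats) and `rejected_count`.
#' @export
clean_nn <- function(rr, bounds = c(300, 2000), max_rel_jump = 0.3) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr
  n <- length(x)
  bad <- x < bounds[1L] | x > bounds[2L]
  if (n >= 3L) {
    for (i in seq_len(n)) {
      idx <- setdiff(order(abs(seq_len(n) - i)), i)[seq_len(min(5L, n - 1L))]
      med <- stats::median(x[idx])
      if (abs(x[i] - med) / med > max_rel_jump) bad[i] <- TRUE
    }
  }
  if (mean(bad) > 0.2) {
    warning(sprintf("%.0f%% of beats rejected: check signal quality",
                    100 * mean(bad)))
  }
  structure(list(nn = x[!bad], t_onset = rr$t_onset[!bad],
                 rejected_count = sum(bad)),
            class = "nn_series")
}

#' Time-domain heart rate variability metrics
#'
#' Mean heart rate and the standard short-term variability statistics:
#' \itemize{
#'   \item `mean_hr`: 60 / mean RR (s), beats/min.
#'   \item `sdrr`, `sdnn`: sample standard deviation (n-1 denominator) of the
#'     RR and NN intervals, ms.
#'   \item `rmssd`: root mean square of successive RR differences, ms.
#'   \item `pnn50`: percentage of successive NN pairs differing by strictly
#'     more than 50 ms, over the n-1 pairs.
#' }
#'
#' @param rr An [rr_series()].
#' @param nn An [clean_nn()] result; defaults to treating `rr` as
#'   already-normal beats.
#' @return Object of class `hrv_time_domain` (a named list). With a single
#'   interval the SD metrics are `NA` and heart rate is still computed.
#' @export
hrv_time_domain <- function(rr, nn = NULL) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr
  nnx <- if (is.null(nn)) x else nn$nn
  out <- list(mean_hr = 60 / (mean(x) / 1000),
              sdrr = NA_real_, sdnn = NA_real_,
              rmssd = NA_real_, pnn50 = NA_real_)
  if (length(x) >= 2L) {
    out$sdrr <- stats::sd(x)
    out$rmssd <- sqrt(mean(diff(x)^2))
  }
  if (length(nnx) >= 2L) {
    out$sdnn <- stats::sd(nnx)
    out$pnn50 <- 100 * sum(abs(diff(nnx)) > 50) / (length(nnx) - 1L)
  }
  class(out) <- "hrv_time_domain"
  out
}

#' @export
print.hrv_time_domain <- function(x, ...) {
  cat(sprintf("HR %.1f bpm | SDRR %.2f ms | SDNN %.2f ms | RMSSD %.2f ms | pNN50 %.1f%%\n",
              x$mean_hr, x$sdrr, x$sdnn, x$rmssd, x$pnn50))
  invisible(x)
}

# canonical HRV band edges (Hz)
hrv_bands <- list(ulf = c(0, 0.003), vlf = c(0.003, 0.04),
                  lf = c(0.04, 0.15), hf = c(0.15, 0.4))

#' Frequency-domain heart rate variability metrics
#'
#' Integrates the RR tachogram power spectral density over the canonical
#' bands: ULF (<= 0.003 Hz), VLF (0.003--0.04), LF (0.04--0.15) and HF
#' (0.15--0.4 Hz). Relative LF and HF powers are taken over the total
#' 0--0.4 Hz power, and LF/HF is reported as a percentage ratio. The PSD of
#' the unevenly sampled tachogram is estimated either by Lomb-Scargle on the
#' beat-stamped intervals (default) or by cubic-spline resampling at 4 Hz
#' followed by a Welch periodogram.
#'
#' @param rr An [rr_series()] (or `nn_series`) of at least 2 minutes for
#'   LF/HF; ULF and VLF are reported `NA` with a reason for records shorter
#'   than 5 minutes.
#' @param method PSD estimator, `"lomb"` or `"welch"`.
#' @return Object of class `hrv_frequency_domain`: band powers in ms^2,
#'   `lf_pct`, `hf_pct` and `lf_hf` in percent, plus `unreliable` naming any
#'   bands suppressed for record length.
#' @export
hrv_frequency_domain <- function(rr, method = c("lomb", "welch")) {
  method <- match.arg(method)
  if (inherits(rr, "nn_series")) {
    t <- rr$t_onset; x <- rr$nn
  } else {
    stopifnot(inherits(rr, "rr_series"))
    t <- rr$t_onset; x <- rr$rr
  }
  span <- t[length(t)] - t[1L]
  if (span < 120) stop("record shorter than 2 minutes: LF/HF unreliable")
  if (stats::sd(x) < 1e-12) {
    sp <- NULL
    pw <- c(ulf = 0, vlf = 0, lf = 0, hf = 0)
  } else if (method == "lomb") {
    sp <- lomb_psd(t, x)
    pw <- vapply(hrv_bands, function(b) band_power(sp$freq, sp$psd, b[1L], b[2L]),
                 numeric(1))
  } else {
    fs <- 4
    tt <- seq(t[1L], t[length(t)], by = 1 / fs)
    xx <- stats::spline(t, x, xout = tt)$y
    seg <- min(length(xx), round(fs * 256))
    sp <- welch_psd(xx, fs, seg_len = seg)
    pw <- vapply(hrv_bands, function(b) band_power(sp$freq, sp$psd, b[1L], b[2L]),
                 numeric(1))
  }
  unreliable <- character(0)
  if (span < 300) {
    unreliable <- c(ulf = "record under 5 minutes", vlf = "record under 5 minutes")
    pw[c("ulf", "vlf")] <- NA_real_
  }
  total <- band_power_total(pw)
  out <- list(ulf = pw[["ulf"]], vlf = pw[["vlf"]], lf = pw[["lf"]], hf = pw[["hf"]],
              lf_pct = if (total > 0) 100 * pw[["lf"]] / total else 0,
              hf_pct = if (total > 0) 100 * pw[["hf"]] / total else 0,
              lf_hf = if (is.finite(pw[["hf"]]) && pw[["hf"]] > 0)
                100 * pw[["lf"]] / pw[["hf"]] else NA_real_,
              method = method, unreliable = unreliable)
  class(out) <- "hrv_frequency_domain"
  out
}

# total 0-0.4 Hz power: the printed relative-power denominator; NA bands
# (suppressed for record length) are excluded from the sum
band_power_total <- function(pw) {
  sum(pw[is.finite(pw)])
}

#' @export
print.hrv_frequency_domain <- function(x, ...) {
  cat(sprintf("LF %.2f ms^2 (%.1f%%) | HF %.2f ms^2 (%.1f%%) | LF/HF %.0f%% [%s]\n",
              x$lf, x$lf_pct, x$hf, x$hf_pct, x$lf_hf, x$method))
  invisible(x)
}

#' Poincare-plot geometric HRV summary
#'
#' Scatter of consecutive intervals RR(i+1) vs RR(i) summarised by the minor
#' and major dispersion axes of the fitted ellipse:
#' \deqn{SD1=\sqrt{0.5\,Var(RR_i - RR_{i+1})},\quad
#'       SD2=\sqrt{0.5\,Var(RR_i + RR_{i+1})}}
#' with the sample (n-1) variance. SD1 reflects short-term, SD2 long-term
#' variability. Per-window summaries over a sliding window are reported
#' alongside the whole-record summary (the default report).
#'
#' @param rr An [rr_series()] with at least 3 intervals per window.
#' @param window Sliding window length in seconds (default 30 s); `Inf`
#'   disables windowing.
#' @return Object of class `poincare_summary`: whole-record `sd1`, `sd2`
#'   (ms), the ellipse centre, an `ellipse` point generator and a `windows`
#'   data frame of per-window summaries.
#' @export
poincare_summary <- function(rr, window = 30) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$rr
  if (length(x) < 3L) stop("need at least 3 intervals")
  sd_pair <- function(v) {
    a <- v[-length(v)]; b <- v[-1L]
    c(sd1 = sqrt(0.5 * stats::var(a - b)), sd2 = sqrt(0.5 * stats::var(a + b)))
  }
  whole <- sd_pair(x)
  centre <- c(mean(x[-length(x)]), mean(x[-1L]))
  windows <- data.frame(t_start = numeric(0), sd1 = numeric(0), sd2 = numeric(0))
  if (is.finite(window)) {
    t <- rr$t_onset
    for (w0 in seq(0, max(0, t[length(t)] - window), by = window)) {
      sel <- t >= w0 & t < w0 + window
      if (sum(sel) >= 3L) {
        s <- sd_pair(x[sel])
        windows <- rbind(windows, data.frame(t_start = w0, sd1 = s[["sd1"]],
                                             sd2 = s[["sd2"]]))
      }
    }
  }
  out <- list(sd1 = whole[["sd1"]], sd2 = whole[["sd2"]], centre = centre,
              windows = windows)
  # parametric ellipse rotated by pi/4 about the centre of mass of the plot
  out$ellipse <- function(theta = seq(0, 2 * pi, length.out = 201L)[-1L]) {
    R <- sqrt(2) / 2 * matrix(c(1, 1, -1, 1), 2, 2)  # rotation by pi/4
    pts <- R %*% rbind(out$sd2 * cos(theta), out$sd1 * sin(theta))
    data.frame(x = pts[1L, ] + centre[1L], y = pts[2L, ] + centre[2L])
  }
  class(out) <- "poincare_summary"
  out
}

#' @export
print.poincare_summary <- function(x, ...) {
  cat(sprintf("SD1 %.2f ms | SD2 %.2f ms | %d windows\n",
              x$sd1, x$sd2, nrow(x$windows)))
  invisible(x)
}
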