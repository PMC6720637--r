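#' Read and write the package's CSV dialects
#'
#' Plain comma-separated UTF-8 files with a mandatory header:
#' \describe{
#'   \item{gaze}{`t,x,y,pupil_radius,valid` — seconds, degrees, mm (empty
#'     field for missing pupil), 0/1 or TRUE/FALSE validity.}
#'   \item{rr}{`rr_ms` — one inter-beat interval (ms) per row.}
#'   \item{resp}{`t,volume_ml`.}
#'   \item{paired}{`t,reference,measured`.}
#'   \item{cluster}{`target_x,target_y,x,y` — one row per gaze sample.}
#' }
#' A header that does not match the schema is an error naming the expected
#' and found columns; malformed (non-numeric) rows are reported with line
#' numbers.
#'
#' @param path File path.
#' @param schema One of `"gaze"`, `"rr"`, `"resp"`, `"paired"`, `"cluster"`.
#' @param sampling_rate Optional declared rate for gaze files (Hz); inferred
#'   from timestamps when omitted.
#' @return The typed series for the schema: a [gaze_stream()], [rr_series()],
#'   [respiration_signal()], [paired_series()] or a list of
#'   [fixation_cluster()] objects (one per distinct target).
#' @export
read_timeseries <- function(path, schema = c("gaze", "rr", "resp", "paired",
                                             "cluster"),
                            sampling_rate = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  expected <- switch(schema,
    gaze = c("t", "x", "y", "pupil_radius", "valid"),
    rr = "rr_ms",
    resp = c("t", "volume_ml"),
    paired = c("t", "reference", "measured"),
    cluster = c("target_x", "target_y", "x", "y"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), expected)) {
    stop(sprintf("header mismatch in %s: expected [%s], found [%s]",
                 path, paste(expected, collapse = ","),
                 paste(names(df), collapse = ",")))
  }
  num_cols <- setdiff(expected, "valid")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !(df[[cn]] %in% c("", "NA", NA)))
    if (length(bad)) {
      stop(sprintf("malformed rows in %s column '%s' (lines %s)", path, cn,
                   paste(utils::head(bad + 1L, 10L), collapse = ", ")))
    }
    df[[cn]] <- v
  }
  switch(schema,
    gaze = gaze_stream(df$t, df$x, df$y,
                       pupil_radius = df$pupil_radius,
                       valid = as.logical(df$valid) |
                         (is.numeric(df$valid) & df$valid != 0),
                       sampling_rate = sampling_rate),
    rr = rr_series(df$rr_ms),
    resp = respiration_signal(df$t, df$volume_ml),
    paired = paired_series(data.frame(t = df$t, value = df$reference),
                           data.frame(t = df$t, value = df$measured)),
    cluster = {
      key <- paste(df$target_x, df$target_y)
      lapply(split(df, key), function(g)
        fixation_cluster(g$x, g$y, g$target_x[1L], g$target_y[1L]))
    })
}

#' @rdname read_timeseries
#' @param x The series object to write.
#' @export
write_timeseries <- function(x, path) {
  if (is_gaze_stream(x)) {
    df <- as.data.frame(x)
  } else if (inherits(x, "rr_series")) {
    df <- data.frame(rr_ms = x$rr)
  } else if (inherits(x, "respiration_signal")) {
    df <- data.frame(t = x$t, volume_ml = x$volume)
  } else if (inherits(x, "paired_series")) {
    df <- data.frame(t = x$t, reference = x$reference, measured = x$measured)
  } else {
    stop("unsupported series type")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Run configuration with ledgered defaults
#'
#' One flat list of every tunable the extraction and inference chain uses,
#' with the package defaults. Unknown keys are rejected, so typos cannot
#' silently fall back to defaults.
#'
#' @param ... Name-value overrides of the defaults.
#' @return A named list of class `cogniphys_config`.
#' @export
#' @examples
#' cogniphys_config(d_max = 1.5)$d_max
cogniphys_config <- function(...) {
  defaults <- list(
    # gaze event detection
    d_max = 1.0,                 # deg, fixation dispersion threshold
    min_duration = 0.1,          # s, minimum fixation duration
    v_threshold = 30,            # deg/s, saccade velocity threshold
    saccade_dur_bounds = c(0.03, 0.08),  # s
    long_fix_threshold = 0.5,    # s, explore/exploit "long" fixation
    blink_max_gap = 0.5,         # s, longest invalid run counted as blink
    pupil_band = c(2, 6),        # Hz
    # cardiorespiratory
    nn_bounds = c(300, 2000),    # ms, physiological RR sanity bounds
    nn_max_rel_jump = 0.3,
    psd_method = "lomb",         # or "welch"
    poincare_window = 30,        # s
    # neuro-fuzzy
    mf_spread_frac = 0.5,        # spread = frac * nearest-centre distance
    calibration_seed = 1L,
    calibration_max_iter = 100L,
    calibration_tol = 1e-8,
    # pipeline epoching
    epoch_window = 60,           # s
    epoch_step = 10,             # s
    # filter chain
    filter_order = 2,
    notch_halfwidth = 2)         # Hz
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(over)] <- over
  class(defaults) <- c("cogniphys_config", "list")
  defaults
}

#' Extract every gaze metric from one stream
#'
#' Runs the full eye-activity chain — blinks, fixations, saccades, dwells,
#' transition matrix — and reports the derived metrics as one flat list.
#'
#' @param stream A [gaze_stream()].
#' @param rois A [roi_layout()], or `NULL` to skip dwell/transition metrics.
#' @param config A [cogniphys_config()].
#' @return Named list of metrics.
#' @export
gaze_report <- function(stream, rois = NULL, config = cogniphys_config()) {
  blinks <- detect_blinks(stream, max_gap = config$blink_max_gap)
  fix <- detect_fixations(stream, d_max = config$d_max,
                          min_duration = config$min_duration)
  sac <- detect_saccades(stream, v_threshold = config$v_threshold,
                         dur_bounds = config$saccade_dur_bounds)
  span <- stream$t[nrow(stream)] - stream$t[1L]
  bm <- blink_metrics(blinks, span)
  out <- list(
    n_fixations = nrow(fix),
    n_saccades = nrow(sac),
    n_blinks = nrow(blinks),
    mean_fixation_duration = if (nrow(fix)) mean(fix$duration) else NA_real_,
    time_to_first_fixation = if (nrow(fix)) time_to_first_fixation(fix, stream$t[1L])
      else NA_real_,
    explore_exploit_ratio = tryCatch(
      explore_exploit_ratio(fix, sac, config$long_fix_threshold),
      error = function(e) NA_real_),
    nni = if (nrow(fix) >= 2L) nearest_neighbour_index(fix) else NA_real_,
    blink_rate = bm$blink_rate,
    percent_closure = bm$percent_closure,
    pupil_band_power = tryCatch(
      pupil_spectral_power(stream, band = config$pupil_band),
      error = function(e) NA_real_))
  if (!is.null(rois)) {
    dw <- segment_dwells(fix, rois)
    tm <- transition_matrix(dw, rois)
    out$n_dwells <- nrow(dw)
    out$visual_entropy <- visual_entropy(tm)
    out$transition_matrix <- tm$P
  }
  out
}
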