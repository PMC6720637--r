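#' Sense-to-estimate pipeline
#'
#' Orchestrates the full chain: per-epoch feature extraction from the
#' cardiorespiratory inputs (heart rate from the RR series, breathing rate
#' from the respiration trace, on sliding windows), followed by fuzzy state
#' inference — with uncertainty propagation when input sigmas are supplied.
#' Alternatively, a precomputed per-epoch feature table can be passed
#' directly. The report embeds a manifest with the exact configuration,
#' seed and package version for reproducibility.
#'
#' @param model A [sugeno_model()].
#' @param features Optional data frame with one row per epoch and columns
#'   matching the model inputs (e.g. from [simulate_workload_session()]).
#' @param rr Optional [rr_series()].
#' @param resp Optional [respiration_signal()].
#' @param sigmas Optional named input 1-sigma uncertainties.
#' @param config A [cogniphys_config()].
#' @param seed Seed recorded in the manifest.
#' @return Object of class `cogniphys_report`: list with `estimates` (data
#'   frame of epoch, inputs, `value`, `sigma`) and `manifest`.
#' @export
run_pipeline <- function(model, features = NULL, rr = NULL, resp = NULL,
                         sigmas = NULL, config = cogniphys_config(),
                         seed = 1L) {
  stopifnot(inherits(model, "sugeno_model"))
  if (is.null(features) && is.null(rr) && is.null(resp)) {
    stop("no modalities: supply features, rr or resp")
  }
  if (is.null(features)) {
    t_end <- max(if (!is.null(rr)) rr$t_onset[length(rr$t_onset)] else 0,
                 if (!is.null(resp)) resp$t[nrow(resp)] else 0)
    starts <- seq(0, max(0, t_end - config$epoch_window), by = config$epoch_step)
    rows <- lapply(starts, function(w0) {
      w1 <- w0 + config$epoch_window
      feat <- list(t = w0)
      if (!is.null(rr)) {
        sel <- rr$t_onset >= w0 & rr$t_onset < w1
        feat$HR <- if (sum(sel) >= 2L) 60 / (mean(rr$rr[sel]) / 1000) else NA_real_
      }
      if (!is.null(resp)) {
        sel <- resp$t >= w0 & resp$t < w1
        feat$BR <- if (sum(sel) >= 8L) {
          sub <- respiration_signal(resp$t[sel], resp$volume[sel])
          tryCatch(respiration_metrics(sub)$br, error = function(e) NA_real_)
        } else NA_real_
      }
      as.data.frame(feat)
    })
    features <- do.call(rbind, rows)
  }
  need <- names(model$inputs)
  missing_in <- setdiff(need, names(features))
  if (length(missing_in)) {
    stop(sprintf("pipeline stage 'features': missing input(s) %s",
                 paste(missing_in, collapse = ", ")))
  }
  est <- lapply(seq_len(nrow(features)), function(i) {
    x <- unlist(features[i, need])
    if (any(!is.finite(x))) return(c(value = NA_real_, sigma = NA_real_))
    e <- tryCatch({
      if (is.null(sigmas)) infer(model, x)
      else propagate_uncertainty(model, x, sigmas)
    }, error = function(err)
      stop(sprintf("pipeline stage 'infer' (epoch %d): %s", i,
                   conditionMessage(err))))
    c(value = e$value, sigma = e$sigma)
  })
  est <- do.call(rbind, est)
  out <- list(
    estimates = cbind(features, value = est[, "value"], sigma = est[, "sigma"]),
    manifest = list(
      package_version = as.character(utils::packageVersion("cogniphys")),
      r_version = R.version.string,
      seed = seed,
      state_name = model$state_name,
      config = unclass(config)))
  class(out) <- "cogniphys_report"
  out
}

#' @export
print.cogniphys_report <- function(x, ...) {
  cat(sprintf("<cogniphys_report> %d epochs of %s\n",
              nrow(x$estimates), x$manifest$state_name))
  print(utils::head(x$estimates))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `cogniphys_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(list(estimates = report$estimates,
                            manifest = report$manifest),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
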