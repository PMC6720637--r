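#' Three-rule mental-workload (MWL) inference model
#'
#' Builds the worked-example Sugeno system relating heart rate (HR, min^-1)
#' and breathing rate (BR, min^-1) to mental workload on a 0--1 scale, from
#' per-participant cluster centres for the low/medium/high task-load
#' conditions (defaults: HR 63.2/64.9/68.3, BR 11.5/14.6/15.3). The three
#' zeroth-order rules are
#' \itemize{
#'   \item if HR is high and BR is low, then MWL = 1
#'   \item if HR is mid and BR is mid, then MWL = 0.5
#'   \item if HR is low and BR is high, then MWL = 0.1
#' }
#' Note the rule base pairs high HR with the *low* BR set even though the
#' high-workload cluster has the highest BR; `rules_from_clusters = TRUE`
#' instead aligns each rule's antecedent labels with its cluster label
#' (high/high, mid/mid, low/low), which is the form used for calibration
#' round trips against simulated sessions.
#'
#' @param family Membership family: `"gaussian"` (required for uncertainty
#'   propagation) or `"trapezoid"` (compact disjoint supports, so exactly one
#'   rule fires at each cluster centre).
#' @param rules_from_clusters Align antecedent labels with cluster labels
#'   instead of using the printed rule base.
#' @param hr_centres,br_centres Cluster centres `(low, mid, high)` per input.
#' @param spread_frac For gaussians, the spread is `spread_frac` times the
#'   distance to the nearest neighbouring centre (default 0.5, i.e. half the
#'   gap). For trapezoids, supports extend `0.8 * spread_frac` times the
#'   smallest adjacent gap either side of the centre, keeping them disjoint.
#' @return A [sugeno_model()] with inputs `HR` and `BR`.
#' @export
#' @examples
#' m <- mwl_example_model(family = "trapezoid")
#' infer(m, c(HR = 68.3, BR = 11.5))$value  # only the first rule fires -> 1
mwl_example_model <- function(family = c("gaussian", "trapezoid"),
                              rules_from_clusters = FALSE,
                              hr_centres = c(low = 63.2, mid = 64.9, high = 68.3),
                              br_centres = c(low = 11.5, mid = 14.6, high = 15.3),
                              spread_frac = 0.5) {
  family <- match.arg(family)
  mk <- function(centres) {
    centres <- sort(centres)  # low < mid < high assumed on entry
    gaps <- diff(centres)
    labs <- names(centres)
    mfs <- list()
    for (i in seq_along(centres)) {
      near <- min(gaps[max(1L, i - 1L):min(length(gaps), i)])
      if (family == "gaussian") {
        mfs[[labs[i]]] <- mf_gaussian(centres[[i]], spread_frac * near)
      } else {
        h <- 0.8 * spread_frac * min(gaps)  # common half-support, disjoint
        mfs[[labs[i]]] <- mf_trapezoid(centres[[i]] - h, centres[[i]] - h / 2,
                                       centres[[i]] + h / 2, centres[[i]] + h)
      }
    }
    mfs
  }
  inputs <- list(HR = mk(hr_centres), BR = mk(br_centres))
  br_labels <- if (rules_from_clusters) c("high", "mid", "low") else
    c("low", "mid", "high")
  rules <- list(
    sugeno_rule(c(HR = "high", BR = br_labels[1L]), 1.0),
    sugeno_rule(c(HR = "mid", BR = br_labels[2L]), 0.5),
    sugeno_rule(c(HR = "low", BR = br_labels[3L]), 0.1))
  sugeno_model(inputs, rules, state_name = "MWL",
               units = c(HR = "min^-1", BR = "min^-1"))
}
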