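#' Define a region-of-interest layout
#'
#' Rectangular, pairwise non-overlapping regions of interest (ROIs) in gaze
#' angle coordinates. Boundaries are closed on the min edges and open on the
#' max edges, so a point exactly on a shared boundary belongs to the
#' lowest-indexed containing ROI.
#'
#' @param roi_id Unique ROI labels.
#' @param x_min,x_max,y_min,y_max Rectangle bounds in degrees.
#' @return A data frame of class `roi_layout`.
#' @export
#' @examples
#' roi_layout(c("PFD", "ND"), x_min = c(-10, 0), x_max = c(0, 10),
#'            y_min = -5, y_max = 5)
roi_layout <- function(roi_id, x_min, x_max, y_min, y_max) {
  out <- data.frame(roi_id = as.character(roi_id),
                    x_min = x_min, x_max = x_max,
                    y_min = y_min, y_max = y_max)
  if (anyDuplicated(out$roi_id)) stop("roi ids must be unique")
  if (any(out$x_max <= out$x_min) || any(out$y_max <= out$y_min)) {
    stop("degenerate ROI rectangle")
  }
  if (nrow(out) > 1L) {
    for (i in seq_len(nrow(out) - 1L)) {
      for (j in (i + 1L):nrow(out)) {
        if (out$x_min[i] < out$x_max[j] && out$x_min[j] < out$x_max[i] &&
            out$y_min[i] < out$y_max[j] && out$y_min[j] < out$y_max[i]) {
          stop(sprintf("ROIs overlap: %s and %s", out$roi_id[i], out$roi_id[j]))
        }
      }
    }
  }
  class(out) <- c("roi_layout", "data.frame")
  out
}

# label of the containing ROI (closed-min, open-max), or NA when outside all
assign_roi <- function(x, y, rois) {
  vapply(seq_along(x), function(i) {
    hit <- which(x[i] >= rois$x_min & x[i] < rois$x_max &
                 y[i] >= rois$y_min & y[i] < rois$y_max)
    if (length(hit)) rois$roi_id[hit[1L]] else NA_character_
  }, character(1))
}

#' Collapse consecutive same-ROI fixations into dwells
#'
#' A dwell is a maximal run of consecutive fixations whose centroids fall in
#' one ROI. Fixations outside every ROI are unassigned and break dwell runs.
#'
#' @param fixations A `fixation_events` frame (ordered).
#' @param rois A [roi_layout()].
#' @return A data frame of class `dwell_events` with columns `roi_id`,
#'   `t_start`, `t_end`, `n_fixations`.
#' @export
segment_dwells <- function(fixations, rois) {
  stopifnot(inherits(rois, "roi_layout"))
  empty <- data.frame(roi_id = character(0), t_start = numeric(0),
                      t_end = numeric(0), n_fixations = integer(0))
  if (nrow(fixations) == 0L) {
    class(empty) <- c("dwell_events", "data.frame"); return(empty)
  }
  lab <- assign_roi(fixations$centroid_x, fixations$centroid_y, rois)
  # run-length encode, treating NA (outside all ROIs) as run breaks
  key <- ifelse(is.na(lab), paste0(".out", seq_along(lab)), lab)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(!startsWith(r$values, ".out"))
  out <- data.frame(roi_id = r$values[keep],
                    t_start = fixations$t_start[starts[keep]],
                    t_end = fixations$t_end[ends[keep]],
                    n_fixations = r$lengths[keep])
  class(out) <- c("dwell_events", "data.frame")
  out
}

#' One-way transition matrix between ROIs
#'
#' Counts transitions between consecutive dwells and normalises each row by
#' the number of transitions leaving that ROI. Self-transitions are
#' impossible by dwell construction, so the diagonal is structurally zero.
#' Per-ROI fixation probabilities are dwell-weighted fixation counts.
#'
#' @param dwells A `dwell_events` frame.
#' @param rois A [roi_layout()] fixing the ROI order.
#' @return An object of class `transition_matrix`: list with `roi_ids`, `P`
#'   (row-stochastic where any transition leaves the ROI, zero diagonal) and
#'   `fixation_probs`.
#' @export
transition_matrix <- function(dwells, rois) {
  ids <- rois$roi_id
  m <- length(ids)
  P <- matrix(0, m, m, dimnames = list(ids, ids))
  counts <- P
  if (nrow(dwells) >= 2L) {
    from <- match(dwells$roi_id[-nrow(dwells)], ids)
    to <- match(dwells$roi_id[-1L], ids)
    for (k in seq_along(from)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
    rs <- rowSums(counts)
    nz <- rs > 0
    P[nz, ] <- counts[nz, , drop = FALSE] / rs[nz]
  }
  fx <- vapply(ids, function(id) sum(dwells$n_fixations[dwells$roi_id == id]),
               numeric(1))
  fixation_probs <- if (sum(fx) > 0) fx / sum(fx) else fx
  structure(list(roi_ids = ids, P = P, fixation_probs = fixation_probs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d ROIs\n", length(x$roi_ids)))
  print(round(x$P, 3))
  invisible(x)
}

#' Visual (gaze transition) entropy
#'
#' Shannon entropy of the ROI-to-ROI transition distribution, weighted by the
#' probability of fixating each source ROI:
#' \deqn{H = -\sum_i p(X_i) \sum_j p(Y_{ij}|X_i)\,\log_2 p(Y_{ij}|X_i)}
#' Terms with zero probability contribute zero. With a zero diagonal the
#' maximum is \eqn{\log_2(m-1)} for `m` ROIs, attained when every row is
#' uniform over its off-diagonal targets.
#'
#' @param tm A [transition_matrix()].
#' @return Entropy in bits.
#' @export
visual_entropy <- function(tm) {
  stopifnot(inherits(tm, "transition_matrix"))
  P <- tm$P
  row_h <- apply(P, 1L, function(p) {
    p <- p[p > 0]
    if (!length(p)) return(0)
    -sum(p * log2(p))
  })
  sum(tm$fixation_probs * row_h)
}

# nearest-neighbour distances for a 2-d point set, chunked to bound memory
nn_distances <- function(x, y, chunk = 512L) {
  n <- length(x)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    dx <- outer(x[i0:i1], x, "-")
    dy <- outer(y[i0:i1], y, "-")
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_len(i1 - i0 + 1L), i0:i1)] <- Inf  # exclude self
    out[i0:i1] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Nearest-neighbour index of fixation locations
#'
#' Ratio of the observed mean nearest-neighbour distance of fixation
#' centroids to the expectation under complete spatial randomness (CSR) over
#' an area A, \eqn{\bar r_E = 0.5\sqrt{A/N}}. Values near 1 indicate random
#' scanning, below 1 clustering, above 1 regular (systematic) scanning.
#'
#' @param fixations A `fixation_events` frame (its centroids are used) or a
#'   two-column matrix/data frame of point coordinates in degrees.
#' @param area Reference area in deg^2; defaults to the bounding box of the
#'   points.
#' @return Dimensionless index, 0 iff all nearest-neighbour distances are 0.
#' @export
nearest_neighbour_index <- function(fixations, area = NULL) {
  if (inherits(fixations, "fixation_events")) {
    x <- fixations$centroid_x; y <- fixations$centroid_y
  } else {
    fixations <- as.matrix(fixations)
    x <- fixations[, 1L]; y <- fixations[, 2L]
  }
  n <- length(x)
  if (n < 2L) stop("need at least 2 fixations")
  if (is.null(area)) area <- (max(x) - min(x)) * (max(y) - min(y))
  if (!is.numeric(area) || area <= 0) stop("area must be > 0")
  r_a <- mean(nn_distances(x, y))
  r_e <- 0.5 * sqrt(area / n)
  r_a / r_e
}
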