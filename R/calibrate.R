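#' Calibrate a Sugeno model against labelled data
#'
#' Offline calibration in the standard two-stage form. Stage one fits the
#' consequent coefficients by linear least squares on the normalised-firing
#' design matrix: for zeroth-order rules the regressors are the normalised
#' weights \eqn{\bar w_k(x)}, for first-order rules
#' \eqn{\bar w_k(x) \cdot (1, x)}. Stage two (optional) refines the premise
#' parameters — Gaussian centres and spreads — by bounded quasi-Newton
#' descent on the residual sum of squares, refitting consequents at each
#' step. Training is deterministic given the seed.
#'
#' @param model A [sugeno_model()] providing the initial premises and the
#'   rule structure (zeroth- or first-order, from the coefficient lengths).
#' @param X Feature matrix or data frame, columns named for the model inputs,
#'   with at least one sample in each rule's region of dominant firing.
#' @param y Numeric target state values.
#' @param refine_premises Also optimise Gaussian premise parameters.
#' @param seed Integer seed (stage two is deterministic but seeded for
#'   reproducibility of any future stochastic refinement).
#' @param max_iter,tol Premise-refinement iteration cap and convergence
#'   tolerance.
#' @return The calibrated `sugeno_model`, with a `fit` attribute carrying the
#'   residual standard deviation.
#' @export
calibrate <- function(model, X, y, refine_premises = FALSE, seed = 1L,
                      max_iter = 100L, tol = 1e-8) {
  stopifnot(inherits(model, "sugeno_model"))
  X <- as.matrix(as.data.frame(X)[, names(model$inputs), drop = FALSE])
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  set.seed(seed)

  fit_consequents <- function(m) {
    W <- firing_strengths(m, X)
    S <- rowSums(W)
    if (any(S <= 0)) stop("some samples fall outside rule coverage")
    Wbar <- W / S
    first_order <- any(vapply(m$rules, function(r) length(r$coeffs) > 1L,
                              logical(1)))
    D <- if (first_order) {
      do.call(cbind, lapply(seq_along(m$rules), function(k)
        Wbar[, k] * cbind(1, X)))
    } else {
      Wbar
    }
    per_rule <- ncol(D) / length(m$rules)
    # a rule whose normalised firing never rises above noise level has no
    # samples in its region of dominant firing
    col_max <- apply(abs(D), 2L, max)
    dead <- unique(ceiling(which(col_max < 1e-6) / per_rule))
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
      dead <- unique(c(dead, ceiling(setdiff(seq_len(ncol(D)),
                                             qrD$pivot[seq_len(qrD$rank)]) / per_rule)))
    }
    if (length(dead)) {
      stop(sprintf("rank-deficient design: rule(s) %s not identifiable",
                   paste(sort(dead), collapse = ", ")))
    }
    beta <- qr.coef(qrD, y)
    per_rule <- ncol(D) / length(m$rules)
    for (k in seq_along(m$rules)) {
      m$rules[[k]]$coeffs <- beta[((k - 1L) * per_rule + 1L):(k * per_rule)]
    }
    resid <- y - as.numeric(D %*% beta)
    attr(m, "fit") <- list(residual_sd = stats::sd(resid))
    m
  }

  model <- fit_consequents(model)

  if (refine_premises) {
    gauss <- all(vapply(model$inputs, function(mfs)
      all(vapply(mfs, function(mf) mf$family == "gaussian", logical(1))),
      logical(1)))
    if (!gauss) stop("premise refinement supports gaussian membership functions only")
    pack <- function(m) {
      unlist(lapply(m$inputs, function(mfs)
        lapply(mfs, function(mf) mf$params)))
    }
    unpack <- function(m, theta) {
      i <- 1L
      for (nm in names(m$inputs)) {
        for (lab in names(m$inputs[[nm]])) {
          m$inputs[[nm]][[lab]] <- mf_gaussian(theta[i], max(theta[i + 1L], 1e-6))
          i <- i + 2L
        }
      }
      m
    }
    theta0 <- pack(model)
    obj <- function(theta) {
      if (any(!is.finite(theta))) return(1e12)
      m <- unpack(model, theta)
      m <- tryCatch(fit_consequents(m), error = function(e) NULL)
      if (is.null(m)) return(1e12)
      attr(m, "fit")$residual_sd^2
    }
    rng <- apply(X, 2L, function(v) diff(range(v))) + 1e-6
    span <- unlist(lapply(names(model$inputs), function(nm)
      rep(rng[[nm]], 2L * length(model$inputs[[nm]]))))
    lower <- theta0 - span
    upper <- theta0 + span
    opt <- tryCatch(
      stats::optim(theta0, obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = max_iter,
                                  factr = tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(opt) && all(is.finite(opt$par))) {
      cand <- tryCatch(fit_consequents(unpack(model, opt$par)),
                       error = function(e) NULL)
      # keep the refinement only when it does not worsen the fit
      if (!is.null(cand) &&
          attr(cand, "fit")$residual_sd <= attr(model, "fit")$residual_sd) {
        model <- cand
      }
    }
  }
  model
}
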