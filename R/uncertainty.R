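#' Propagate input measurement uncertainty to the state estimate
#'
#' First-order (delta-method) propagation of independent 1-sigma input
#' uncertainties through the five inference layers. Writing
#' \eqn{y = \sum_k \bar w_k f_k(x)} with normalised firing strengths
#' \eqn{\bar w_k}, the output variance decomposes into a normalisation-layer
#' term driven by the rule-weight sensitivities and a consequent-layer term
#' driven by the polynomial slopes:
#' \deqn{\sigma_y^2 \;=\; \sum_i \Big(\sum_k f_k \tfrac{\partial \bar w_k}{\partial x_i}\Big)^2 \sigma_{x_i}^2
#'  \;+\; \sum_k \bar w_k^2 \sum_i (p_{ki}\,\sigma_{x_i})^2}
#' where \eqn{\partial \bar w_k/\partial x_i = \bar w_k (g_{ki} - \sum_l \bar w_l\, g_{li})}
#' and \eqn{g_{ki} = \partial \ln \mu_{A_{ik}}(x_i)/\partial x_i}. Because
#' the normalised weights sum to one, their sensitivities to a common input
#' are fully (negatively) correlated across rules; the default `"first_order"`
#' method keeps that correlation, which is what a Monte-Carlo propagation
#' converges to as the input sigmas shrink. The `"independent_rules"` method
#' instead adds the per-rule terms \eqn{(f_k \sigma_{\bar w_k})^2} in
#' quadrature, treating the rule-weight uncertainties as uncorrelated — an
#' upper-bound style book-keeping that some uncertainty budgets use.
#' Alternatively, known normalisation-layer uncertainties
#' \eqn{\sigma_{\bar w_k}} can be supplied directly via `sigma_wbar` and are
#' then combined in quadrature with the consequent term.
#'
#' @param model A [sugeno_model()] whose membership functions are Gaussian
#'   (or sigmoid), so the fuzzification layer is differentiable.
#' @param x Named numeric vector of input values.
#' @param sigma Named numeric vector of 1-sigma input uncertainties (same
#'   units as `x`), all nonnegative.
#' @param method `"first_order"` (default) or `"independent_rules"`, see
#'   above.
#' @param sigma_wbar Optional per-rule normalised-weight uncertainties,
#'   overriding the delta-method values.
#' @return A `state_estimate` with its `sigma` field populated; zero when all
#'   input sigmas are zero.
#' @export
#' @examples
#' m <- mwl_example_model()
#' propagate_uncertainty(m, c(HR = 64.9, BR = 14.6), c(HR = 5.5, BR = 1.6))
propagate_uncertainty <- function(model, x, sigma,
                                  method = c("first_order", "independent_rules"),
                                  sigma_wbar = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(model, "sugeno_model"))
  nms <- names(model$inputs)
  if (!all(nms %in% names(sigma))) stop("sigma must name every model input")
  if (any(sigma[nms] < 0)) stop("input sigmas must be nonnegative")
  est <- infer(model, x)
  wbar <- est$normalized_weights
  K <- length(model$rules)
  n_in <- length(nms)
  X <- matrix(x[nms], 1L, dimnames = list(NULL, nms))
  f <- consequent_values(model, X)[1L, ]

  # g[k, i] = d ln mu_{A_ik} / d x_i (zero when input i is absent from rule k)
  g <- matrix(0, K, n_in, dimnames = list(NULL, nms))
  for (k in seq_len(K)) {
    ant <- model$rules[[k]]$antecedent
    for (nm in names(ant)) {
      mf <- model$inputs[[nm]][[ant[[nm]]]]
      mu <- membership(mf, x[[nm]])
      g[k, nm] <- if (mu > 0) membership_grad(mf, x[[nm]]) / mu else 0
    }
  }
  # dwbar[k, i] = d wbar_k / d x_i
  dwbar <- wbar * (g - matrix(colSums(wbar * g), K, n_in, byrow = TRUE))

  # consequent-layer slopes, zero for zeroth-order rules
  P <- matrix(0, K, n_in, dimnames = list(NULL, nms))
  for (k in seq_len(K)) {
    cf <- model$rules[[k]]$coeffs
    if (length(cf) > 1L) P[k, ] <- cf[-1L]
  }
  cons_var <- sum(wbar^2 * as.numeric((P^2) %*% (sigma[nms]^2)))

  if (!is.null(sigma_wbar)) {
    stopifnot(length(sigma_wbar) == K, all(sigma_wbar >= 0))
    norm_var <- sum((f * sigma_wbar)^2)
  } else if (method == "independent_rules") {
    s_wbar <- sqrt(as.numeric((dwbar^2) %*% (sigma[nms]^2)))
    norm_var <- sum((f * s_wbar)^2)
  } else {
    dy <- as.numeric(t(dwbar) %*% f)  # d y / d x_i from the weight layer
    norm_var <- sum((dy * sigma[nms])^2)
  }
  est$sigma <- sqrt(norm_var + cons_var)
  est
}

#' Uncertainty surface over an input grid
#'
#' Evaluates the crisp state estimate and its propagated 1-sigma uncertainty
#' on a rectangular grid, the standard view for locating high-uncertainty
#' regions — typically where neighbouring rules conflict, i.e. between
#' cluster centres rather than at them.
#'
#' @param model A [sugeno_model()] with Gaussian membership functions.
#' @param grid Named list of per-input grid vectors.
#' @param sigmas Named vector of input 1-sigma uncertainties.
#' @param method Passed to [propagate_uncertainty()].
#' @return Data frame: one row per grid point with the input coordinates,
#'   `value` and `sigma`.
#' @export
uncertainty_surface <- function(model, grid, sigmas,
                                method = c("first_order", "independent_rules")) {
  method <- match.arg(method)
  stopifnot(length(grid) >= 1L, all(names(model$inputs) %in% names(grid)))
  pts <- expand.grid(grid[names(model$inputs)], KEEP.OUT.ATTRS = FALSE)
  out <- cbind(pts, value = NA_real_, sigma = NA_real_)
  for (r in seq_len(nrow(pts))) {
    x <- unlist(pts[r, ])
    est <- tryCatch(propagate_uncertainty(model, x, sigmas, method = method),
                    error = function(e) NULL)
    if (!is.null(est)) {
      out$value[r] <- est$value
      out$sigma[r] <- est$sigma
    }
  }
  out
}
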