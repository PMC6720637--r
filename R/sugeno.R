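#' Sugeno-type fuzzy rules and models
#'
#' A Sugeno rule pairs an antecedent — one labelled membership function per
#' input, combined with the product AND operator — with a polynomial
#' consequent \eqn{f_k = p_{k0} + p_{k1} x_1 + \dots + p_{ki} x_i}. A
#' zeroth-order rule carries only the constant \eqn{p_{k0}}.
#'
#' @param antecedent Named character vector mapping input name to a
#'   membership-function label declared for that input.
#' @param coeffs Consequent coefficients `(p0)` for a zeroth-order rule or
#'   `(p0, p1, ..., pi)` for a first-order rule.
#' @return A `sugeno_rule`.
#' @export
sugeno_rule <- function(antecedent, coeffs) {
  stopifnot(length(antecedent) >= 1L, !is.null(names(antecedent)),
            length(coeffs) >= 1L)
  structure(list(antecedent = antecedent, coeffs = as.numeric(coeffs)),
            class = "sugeno_rule")
}

#' @rdname sugeno_rule
#' @param inputs Named list: one element per input, itself a named list of
#'   [membership_function][mf_trapezoid] objects keyed by label. Optionally
#'   each input list carries a `unit` attribute.
#' @param rules List of `sugeno_rule` objects; every referenced label must
#'   exist in the input's membership inventory.
#' @param state_name Name of the estimated cognitive state (e.g. `"MWL"`).
#' @param units Optional named character vector of input units.
#' @return For `sugeno_model()`, a `sugeno_model` object.
#' @export
sugeno_model <- function(inputs, rules, state_name = "state", units = NULL) {
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)), length(rules) >= 1L)
  n_in <- length(inputs)
  for (r in rules) {
    stopifnot(inherits(r, "sugeno_rule"))
    if (!all(names(r$antecedent) %in% names(inputs))) {
      stop("rule references undeclared input")
    }
    for (nm in names(r$antecedent)) {
      if (!r$antecedent[[nm]] %in% names(inputs[[nm]])) {
        stop(sprintf("rule references unknown membership label '%s' for input '%s'",
                     r$antecedent[[nm]], nm))
      }
    }
    if (!length(r$coeffs) %in% c(1L, n_in + 1L)) {
      stop("consequent must have 1 (zeroth-order) or n_inputs+1 coefficients")
    }
  }
  structure(list(inputs = inputs, rules = rules, state_name = state_name,
                 units = units, and_operator = "product"),
            class = "sugeno_model")
}

#' @export
print.sugeno_model <- function(x, ...) {
  cat(sprintf("<sugeno_model> '%s': %d inputs (%s), %d rules\n",
              x$state_name, length(x$inputs),
              paste(names(x$inputs), collapse = ", "), length(x$rules)))
  for (k in seq_along(x$rules)) {
    r <- x$rules[[k]]
    ant <- paste(sprintf("%s is %s", names(r$antecedent), r$antecedent),
                 collapse = " and ")
    cons <- if (length(r$coeffs) == 1L) sprintf("%g", r$coeffs) else
      paste0(sprintf("%g", r$coeffs[1L]), " + ",
             paste(sprintf("%g*%s", r$coeffs[-1L], names(x$inputs)),
                   collapse = " + "))
    cat(sprintf("  R%d: if %s then %s = %s\n", k, ant, x$state_name, cons))
  }
  invisible(x)
}

# firing strengths for a matrix of inputs (rows = samples, named columns);
# returns samples x rules matrix of products of memberships
firing_strengths <- function(model, X) {
  X <- as.matrix(X)
  K <- length(model$rules)
  W <- matrix(1, nrow(X), K)
  for (k in seq_len(K)) {
    ant <- model$rules[[k]]$antecedent
    for (nm in names(ant)) {
      W[, k] <- W[, k] * membership(model$inputs[[nm]][[ant[[nm]]]], X[, nm])
    }
  }
  W
}

# per-rule consequent values f_k(x) for a matrix of inputs
consequent_values <- function(model, X) {
  X <- as.matrix(X)
  K <- length(model$rules)
  Fv <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    cf <- model$rules[[k]]$coeffs
    Fv[, k] <- cf[1L]
    if (length(cf) > 1L) {
      Fv[, k] <- Fv[, k] + as.numeric(X[, names(model$inputs), drop = FALSE] %*%
                                        cf[-1L])
    }
  }
  Fv
}

#' Sugeno inference
#'
#' Evaluates the five-layer neuro-fuzzy network: fuzzification of each input,
#' product-AND rule firing strengths \eqn{w_k = \prod_i \mu_{A_{ik}}(x_i)},
#' normalisation \eqn{\bar w_k = w_k / \sum_k w_k}, per-rule consequents, and
#' the weighted-average defuzzified output
#' \eqn{y = \sum_k \bar w_k f_k(x)} — a convex combination of the rule
#' outputs.
#'
#' @param model A [sugeno_model()].
#' @param x Named numeric vector matching the model inputs.
#' @return A `state_estimate`: list with `state_name`, `value`, `sigma`
#'   (`NA` here; see [propagate_uncertainty()]), `firing_strengths` and
#'   `normalized_weights`.
#' @export
#' @examples
#' m <- mwl_example_model()
#' infer(m, c(HR = 64.9, BR = 14.6))$value
infer <- function(model, x) {
  stopifnot(inherits(model, "sugeno_model"))
  if (!all(names(model$inputs) %in% names(x))) {
    stop("input vector must name every model input")
  }
  X <- matrix(x[names(model$inputs)], 1L,
              dimnames = list(NULL, names(model$inputs)))
  w <- firing_strengths(model, X)[1L, ]
  S <- sum(w)
  if (S <= 0) stop("input outside rule coverage: all firing strengths zero")
  wbar <- w / S
  f <- consequent_values(model, X)[1L, ]
  structure(list(state_name = model$state_name,
                 value = sum(wbar * f), sigma = NA_real_,
                 firing_strengths = w, normalized_weights = wbar),
            class = "state_estimate")
}

#' @export
print.state_estimate <- function(x, ...) {
  if (is.na(x$sigma)) {
    cat(sprintf("%s = %.4g\n", x$state_name, x$value))
  } else {
    cat(sprintf("%s = %.4g +/- %.4g (1-sigma)\n", x$state_name, x$value, x$sigma))
  }
  invisible(x)
}

#' Serialise / deserialise a Sugeno model as JSON
#'
#' The on-disk layout is
#' `{state_name, inputs:[{name, unit, mfs:[{label, family, params}]}],`
#' `rules:[{antecedent:{input: label}, coeffs:[...]}]}`. The round trip is
#' lossless.
#'
#' @param model A [sugeno_model()].
#' @param path File path.
#' @return `read_sugeno_model()` returns the model; `write_sugeno_model()`
#'   its path, invisibly.
#' @export
write_sugeno_model <- function(model, path) {
  obj <- list(
    state_name = model$state_name,
    inputs = lapply(names(model$inputs), function(nm) {
      list(name = nm,
           unit = if (!is.null(model$units)) model$units[[nm]] else "",
           mfs = lapply(names(model$inputs[[nm]]), function(lab) {
             mf <- model$inputs[[nm]][[lab]]
             list(label = lab, family = mf$family, params = as.list(mf$params))
           }))
    }),
    rules = lapply(model$rules, function(r) {
      list(antecedent = as.list(r$antecedent), coeffs = r$coeffs)
    })
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_sugeno_model
#' @export
read_sugeno_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  inputs <- list(); units <- character(0)
  for (inp in obj$inputs) {
    mfs <- list()
    for (m in inp$mfs) {
      p <- m$params
      mfs[[m$label]] <- switch(m$family,
        trapezoid = mf_trapezoid(p$a, p$b, p$c, p$d),
        gaussian = mf_gaussian(p$c, p$sigma),
        sigmoid = mf_sigmoid(p$a, p$c),
        stop("unknown membership family in model file"))
    }
    inputs[[inp$name]] <- mfs
    units[[inp$name]] <- if (is.null(inp$unit)) "" else inp$unit
  }
  rules <- lapply(obj$rules, function(r) {
    sugeno_rule(unlist(r$antecedent), unlist(r$coeffs))
  })
  sugeno_model(inputs, rules, state_name = obj$state_name, units = units)
}
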