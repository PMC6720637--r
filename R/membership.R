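#' Fuzzy membership functions
#'
#' Constructors for the three membership-function families used by the
#' inference engine. Parameters are validated at construction time, never at
#' evaluation time. All families map the real line into \[0, 1\].
#'
#' \describe{
#'   \item{trapezoid}{`(a, b, c, d)` with `a < b <= c < d`: 0 outside
#'     `[a, d]`, 1 on `[b, c]`, linear ramps between. A triangular set is the
#'     special case `b == c`.}
#'   \item{gaussian}{`(c, sigma)`: `exp(-(x - c)^2 / (2 sigma^2))`, peak 1 at
#'     `x = c`.}
#'   \item{sigmoid}{`(a, c)`: `1 / (1 + exp(-a (x - c)))`, value 0.5 at the
#'     inflection `x = c`.}
#' }
#'
#' @param a,b,c,d,sigma Family parameters, see above.
#' @return An object of class `membership_function`.
#' @export
#' @examples
#' membership(mf_gaussian(64.9, 2), 64.9)   # 1 at the centre
#' membership(mf_trapezoid(0, 1, 2, 3), 0.5)
mf_trapezoid <- function(a, b, c, d) {
  if (!(a < b && b <= c && c < d)) stop("trapezoid requires a < b <= c < d")
  structure(list(family = "trapezoid", params = c(a = a, b = b, c = c, d = d)),
            class = "membership_function")
}

#' @rdname mf_trapezoid
#' @export
mf_gaussian <- function(c, sigma) {
  if (sigma <= 0) stop("gaussian requires sigma > 0")
  structure(list(family = "gaussian", params = c(c = c, sigma = sigma)),
            class = "membership_function")
}

#' @rdname mf_trapezoid
#' @export
mf_sigmoid <- function(a, c) {
  if (a == 0) stop("sigmoid requires a != 0")
  structure(list(family = "sigmoid", params = c(a = a, c = c)),
            class = "membership_function")
}

#' @rdname mf_trapezoid
#' @param mf A `membership_function`.
#' @param x Numeric vector of input values.
#' @return For `membership()`, membership degrees in \[0, 1\].
#' @export
membership <- function(mf, x) {
  stopifnot(inherits(mf, "membership_function"))
  p <- mf$params
  switch(mf$family,
    trapezoid = {
      y <- numeric(length(x))
      up <- x > p[["a"]] & x < p[["b"]]
      y[up] <- (x[up] - p[["a"]]) / (p[["b"]] - p[["a"]])
      y[x >= p[["b"]] & x <= p[["c"]]] <- 1
      dn <- x > p[["c"]] & x < p[["d"]]
      y[dn] <- (p[["d"]] - x[dn]) / (p[["d"]] - p[["c"]])
      y
    },
    gaussian = exp(-(x - p[["c"]])^2 / (2 * p[["sigma"]]^2)),
    sigmoid = 1 / (1 + exp(-p[["a"]] * (x - p[["c"]])))
  )
}

# d(membership)/dx, used by first-order uncertainty propagation
membership_grad <- function(mf, x) {
  p <- mf$params
  switch(mf$family,
    gaussian = {
      mu <- exp(-(x - p[["c"]])^2 / (2 * p[["sigma"]]^2))
      -mu * (x - p[["c"]]) / p[["sigma"]]^2
    },
    sigmoid = {
      mu <- 1 / (1 + exp(-p[["a"]] * (x - p[["c"]])))
      p[["a"]] * mu * (1 - mu)
    },
    stop("analytic gradient available for gaussian and sigmoid families only")
  )
}

#' @export
print.membership_function <- function(x, ...) {
  cat(sprintf("<membership_function> %s(%s)\n", x$family,
              paste(sprintf("%s=%g", names(x$params), x$params), collapse = ", ")))
  invisible(x)
}
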