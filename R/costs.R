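#' Behavioral cost specifications
#'
#' A cost specification maps a circular estimation error to a behavioral
#' cost. Available families:
#'
#' * `"power"`: `|eps|^beta` with exponent `beta > 0` (the default family;
#'   `beta` is a free parameter when fitting).
#' * `"abs"`, `"squared"`, `"neg_cosine"`: the parameter-free choices
#'   `|eps|`, `eps^2` and `-cos(eps)`.
#' * `"saturating"`: a two-parameter saturating map
#'   `1 - exp(-(|eps| / scale)^shape)`, which flattens out for large errors.
#' * `"binary_threshold"`: 0 for `|eps| < threshold`, 1 otherwise, emulating
#'   binary ("correct"/"error") feedback with feedback threshold `threshold`
#'   in radians.
#'
#' Every family is even in `eps` and attains its minimum at `eps = 0`.
#'
#' @param family One of `"power"`, `"abs"`, `"squared"`, `"neg_cosine"`,
#'   `"saturating"`, `"binary_threshold"`.
#' @param beta Exponent for the power family (> 0).
#' @param scale,shape Parameters of the saturating family (> 0).
#' @param threshold Feedback threshold in radians for the binary family,
#'   in `(0, pi)`.
#' @return An object of class `cost_spec`.
#' @export
#' @examples
#' cost_spec("power", beta = 2)
#' cost_spec("binary_threshold", threshold = pi / 3)
cost_spec <- function(family = c("power", "abs", "squared", "neg_cosine",
                                 "saturating", "binary_threshold"),
                      beta = 2, scale = 1, shape = 2, threshold = pi / 3) {
  family <- match.arg(family)
  params <- switch(family,
    power = {
      if (!is.finite(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
      c(beta = beta)
    },
    saturating = {
      if (scale <= 0 || shape <= 0) stop("saturating parameters must be > 0", call. = FALSE)
      c(scale = scale, shape = shape)
    },
    binary_threshold = {
      if (!is.finite(threshold) || threshold <= 0 || threshold > pi) {
        stop("`threshold` must lie in (0, pi]", call. = FALSE)
      }
      c(threshold = threshold)
    },
    numeric(0)
  )
  structure(list(family = family, params = params), class = "cost_spec")
}

#' @export
print.cost_spec <- function(x, ...) {
  cat("<cost_spec> family:", x$family)
  if (length(x$params)) {
    cat(" (", paste(names(x$params), signif(x$params, 4), sep = " = ",
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# integer code + parameter vector for the C++ kernels
cost_code <- function(cost) {
  stopifnot(inherits(cost, "cost_spec"))
  code <- match(cost$family, c("power", "abs", "squared", "neg_cosine",
                               "saturating", "binary_threshold"))
  list(code = as.integer(code), params = as.numeric(cost$params))
}

# number of free parameters a cost family contributes to a fitted model
cost_n_free <- function(cost) {
  switch(cost$family, power = 1L, saturating = 2L, 0L)
}

#' Pointwise behavioral cost
#'
#' Evaluates the cost of each error under a [cost_spec()].
#'
#' @param epsilon Errors in radians (wrapped internally).
#' @param cost A [cost_spec()].
#' @return Numeric vector of costs.
#' @export
#' @examples
#' behavioral_cost(c(0, pi / 2, pi), cost_spec("neg_cosine"))
behavioral_cost <- function(epsilon, cost) {
  cc <- cost_code(cost)
  ae <- abs(wrap_angle(epsilon))
  switch(cost$family,
    power = ae^cost$params[["beta"]],
    abs = ae,
    squared = ae^2,
    neg_cosine = -cos(ae),
    saturating = 1 - exp(-(ae / cost$params[["scale"]])^cost$params[["shape"]]),
    binary_threshold = as.numeric(ae >= cost$params[["threshold"]])
  )
}

#' Expected behavioral cost as a function of mean precision
#'
#' Integrates the pointwise cost against the predicted error density
#' `p(eps; j_bar, tau)` (see [predicted_error_pdf()]). Smooth families use a
#' composite trapezoid rule on `[0, pi]` doubled by symmetry; the
#' binary-threshold family uses exact Von Mises CDF masses of each mixture
#' component so the discontinuity introduces no quadrature error. The result
#' is non-increasing in `j_bar` for the power, abs, squared and neg_cosine
#' families.
#'
#' @param j_bar Vector of non-negative mean precisions.
#' @param tau Non-negative precision variability.
#' @param cost A [cost_spec()].
#' @param n_eps Number of trapezoid points on `[0, pi]` (default 2000).
#' @param n_bins Number of gamma discretization bins (default 50).
#' @return Expected cost for each element of `j_bar`.
#' @export
#' @examples
#' expected_behavioral_cost(0, tau = 0, cost_spec("squared"))  # pi^2 / 3
expected_behavioral_cost <- function(j_bar, tau, cost,
                                     n_eps = .rrvwm$n_eps,
                                     n_bins = .rrvwm$n_bins) {
  stopifnot(is.numeric(j_bar), all(is.finite(j_bar)), all(j_bar >= 0),
            length(tau) == 1L, is.finite(tau), tau >= 0)
  cc <- cost_code(cost)
  out <- cpp_cbar(as.numeric(j_bar), tau, cc$code, cc$params,
                  as.integer(n_bins), as.integer(n_eps), .rrvwm$tau_floor)
  if (any(!is.finite(out))) stop("expected-cost quadrature failed to converge",
                                 call. = FALSE)
  out
}

#' Derivative of the expected behavioral cost
#'
#' Numerical derivative of [expected_behavioral_cost()] with respect to
#' `j_bar`, by central differences (one-sided at `j_bar = 0`). Some cost
#' families have an unbounded slope at zero (e.g. the equal-precision power
#' family, where `kappa ~ sqrt(2 J)` makes `d kappa / d J` blow up); when
#' the one-sided slope magnitude exceeds `1e8` at step `1e-6` the derivative
#' is reported as `-Inf`.
#'
#' @inheritParams expected_behavioral_cost
#' @param j_bar Scalar non-negative mean precision.
#' @return The derivative (possibly `-Inf`).
#' @export
#' @examples
#' expected_cost_derivative(5, tau = 1, cost_spec("power", beta = 2))
expected_cost_derivative <- function(j_bar, tau, cost,
                                     n_eps = .rrvwm$n_eps,
                                     n_bins = .rrvwm$n_bins) {
  stopifnot(length(j_bar) == 1L, is.finite(j_bar), j_bar >= 0)
  cbar <- function(j) expected_behavioral_cost(j, tau, cost,
                                               n_eps = n_eps, n_bins = n_bins)
  if (j_bar == 0) {
    c0 <- cbar(0)
    s1 <- (cbar(1e-6) - c0) / 1e-6
    s2 <- (cbar(2.5e-7) - c0) / 2.5e-7
    # unbounded slope at zero: magnitude blow-up or growth under step halving
    # (a square-root singularity doubles the one-sided slope per 4x step cut)
    if (abs(s2) > 1e8 || (abs(s1) > 1e-3 && abs(s2) > 1.8 * abs(s1))) {
      return(-Inf)
    }
    # finite slope: step out of the quadrature noise floor before estimating
    h <- 1e-6
    while (abs(cbar(h) - c0) < 1e-5 * max(1, abs(c0)) && h < 1e-2) h <- h * 10
    sa <- (cbar(h) - c0) / h
    sb <- (cbar(h / 2) - c0) / (h / 2)
    return(2 * sb - sa)
  }
  h <- max(1e-6, 1e-4 * j_bar)
  h <- min(h, j_bar)  # keep the lower point non-negative
  (cbar(j_bar + h) - cbar(j_bar - h)) / (2 * h)
}

#' Expected neural cost of a display
#'
#' The expected neural cost of encoding a display is linear in the invested
#' resource: `alpha * sum(j_bar)`, independent of the variability `tau`.
#' `alpha` is fixed to 1 throughout (it trades off against the weight
#' `lambda`).
#'
#' @param j_bar Vector of non-negative mean precisions, one per item.
#' @param alpha Cost per unit of precision (default 1).
#' @return The scalar expected neural cost.
#' @export
#' @examples
#' display_neural_cost(c(2, 3))
display_neural_cost <- function(j_bar, alpha = 1) {
  stopifnot(is.numeric(j_bar))
  if (any(j_bar < 0)) stop("`j_bar` entries must be non-negative", call. = FALSE)
  alpha * sum(j_bar)
}
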