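#' Resource-rational model parameters
#'
#' Bundles the parameters of the resource-rational observer: the neural-cost
#' weight `lambda` (cost per unit of invested precision, relative to the
#' behavioral cost), the precision variability `tau`, and a behavioral
#' [cost_spec()]. The per-unit neural cost `alpha` is fixed to 1; it is
#' redundant with `lambda`.
#'
#' @param lambda Non-negative neural-cost weight.
#' @param tau Non-negative precision variability (gamma scale).
#' @param cost A [cost_spec()]; default power-law cost with `beta = 2`.
#' @param alpha Neural cost per unit precision, fixed to 1.
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params(lambda = 0.01, tau = 0, cost = cost_spec("power", beta = 2))
model_params <- function(lambda, tau, cost = cost_spec("power", beta = 2),
                         alpha = 1) {
  stopifnot(is.finite(lambda), lambda >= 0, is.finite(tau), tau >= 0,
            inherits(cost, "cost_spec"), alpha == 1)
  structure(list(lambda = lambda, tau = tau, cost = cost, alpha = alpha),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> lambda =", signif(x$lambda, 4),
      " tau =", signif(x$tau, 4), "\n")
  print(x$cost)
  invisible(x)
}

#' Optimal per-item resource
#'
#' Minimizes the expected total cost per item,
#' `f(J) = p * cbar(J; tau) + lambda * J`, over `J >= 0`, where `cbar` is the
#' expected behavioral cost ([expected_behavioral_cost()]). The search scans
#' 200 log-spaced points on `[1e-6, 1e5]`, refines the best interior point by
#' Brent search in `log J`, and compares the result against the boundary
#' `J = 0`. If the objective is still decreasing at the upper search bound
#' (e.g. when `lambda = 0` and `p > 0`), the minimum is unbounded and `Inf`
#' is returned.
#'
#' @param p Probing probability (or item relevance), vectorized, in `[0, 1]`.
#' @param params A [model_params()].
#' @param n_eps,n_bins Quadrature resolution passed to the expected-cost
#'   integral.
#' @param n_grid Number of log-spaced scan points.
#' @return Optimal mean precision for each `p`; `Inf` flags an unbounded
#'   optimum.
#' @export
#' @examples
#' pars <- model_params(lambda = 0.01, tau = 0)
#' optimal_resource(c(0.125, 0.25, 0.5, 1), pars)
optimal_resource <- function(p, params, n_eps = .rrvwm$n_eps,
                             n_bins = .rrvwm$n_bins, n_grid = 200) {
  stopifnot(inherits(params, "model_params"),
            is.numeric(p), all(is.finite(p)), all(p >= 0), all(p <= 1))
  up <- unique(p)
  j_grid <- exp(seq(log(.rrvwm$j_lower), log(.rrvwm$j_upper),
                    length.out = n_grid))
  cb <- expected_behavioral_cost(j_grid, params$tau, params$cost,
                                 n_eps = n_eps, n_bins = n_bins)
  cb0 <- expected_behavioral_cost(0, params$tau, params$cost,
                                  n_eps = n_eps, n_bins = n_bins)
  res <- vapply(up, function(pi) {
    if (pi == 0) return(0)
    if (params$lambda == 0) return(Inf)
    f <- pi * cb + params$lambda * j_grid
    f0 <- pi * cb0
    k <- which.min(f)
    if (k == n_grid && f[n_grid] < f[n_grid - 1] && f[n_grid] < f0) {
      return(Inf)  # still decreasing at the upper bound
    }
    lo <- log(j_grid[max(1, k - 1)])
    hi <- log(j_grid[min(n_grid, k + 1)])
    obj <- function(s) {
      j <- exp(s)
      pi * expected_behavioral_cost(j, params$tau, params$cost,
                                    n_eps = n_eps, n_bins = n_bins) +
        params$lambda * j
    }
    opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
    j_star <- exp(opt$minimum)
    if (f0 <= opt$objective) 0 else j_star
  }, numeric(1))
  res[match(p, up)]
}

#' Probing-probability regime thresholds
#'
#' The domain of probing probability splits into up to three regimes:
#' below `p0` it is optimal to invest nothing, between `p0` and `p_inf`
#' a finite amount, and above `p_inf` an unbounded amount. The thresholds
#' follow from the first-order condition of the per-item objective at its
#' boundaries: `p0 = lambda / |cbar'(0)|` and `p_inf = lambda / |cbar'(Inf)|`
#' (each may exceed 1, in which case the later regimes do not exist). Both
#' are cross-checked by bisection on `p` of the indicator that
#' [optimal_resource()] is strictly positive (resp. bounded); a divergent
#' slope at zero forces `p0 = 0` and a vanishing slope at infinity forces
#' `p_inf = Inf`.
#'
#' @param params A [model_params()].
#' @param bisect_tol Bisection tolerance on `p`.
#' @param n_eps,n_bins Quadrature resolution.
#' @return A one-row tibble with columns `p0`, `p_inf` (ratio form) and
#'   `p0_bisect`, `p_inf_bisect` (bisection on `[0, 1]`; `NA` when the
#'   threshold lies outside `[0, 1]`).
#' @export
#' @examples
#' \donttest{
#' thresholds(model_params(lambda = 0.01, tau = 20))
#' }
thresholds <- function(params, bisect_tol = 1e-6,
                       n_eps = .rrvwm$n_eps, n_bins = .rrvwm$n_bins) {
  stopifnot(inherits(params, "model_params"))
  if (params$lambda == 0) {
    return(tibble::tibble(p0 = 0, p_inf = 0, p0_bisect = 0, p_inf_bisect = 0))
  }
  d0 <- expected_cost_derivative(0, params$tau, params$cost,
                                 n_eps = n_eps, n_bins = n_bins)
  if (is.infinite(d0)) {
    p0 <- 0
  } else {
    # p0 = lambda / |cbar'(0)| under diminishing returns; computed in its
    # exact global form lambda / sup_J [(cbar(0) - cbar(J)) / J], which is
    # what the indicator [J_opt(p) > 0] actually thresholds (the two
    # coincide when the slope magnitude is largest at J = 0)
    jg <- exp(seq(log(.rrvwm$j_lower), log(.rrvwm$j_upper), length.out = 400))
    cb <- expected_behavioral_cost(jg, params$tau, params$cost,
                                   n_eps = n_eps, n_bins = n_bins)
    cb0 <- expected_behavioral_cost(0, params$tau, params$cost,
                                    n_eps = n_eps, n_bins = n_bins)
    g <- (cb0 - cb) / jg
    k <- which.max(g)
    ref <- stats::optimize(function(s) {
      j <- exp(s)
      -(cb0 - expected_behavioral_cost(j, params$tau, params$cost,
                                       n_eps = n_eps, n_bins = n_bins)) / j
    }, lower = log(jg[max(1, k - 1)]), upper = log(jg[min(400, k + 1)]),
    tol = 1e-8)
    gmax <- max(g, -ref$objective, abs(d0))
    p0 <- if (gmax <= 0) Inf else params$lambda / gmax
  }
  # slope at "infinity": evaluate at the top of the search range
  d_inf <- expected_cost_derivative(.rrvwm$j_upper, params$tau, params$cost,
                                    n_eps = n_eps, n_bins = n_bins)
  p_inf <- if (abs(d_inf) < 1e-12) Inf else params$lambda / abs(d_inf)

  jopt <- function(pr) optimal_resource(pr, params, n_eps = n_eps,
                                        n_bins = n_bins)
  bisect <- function(pred) {
    # infimum p in [0, 1] at which pred(p) becomes TRUE
    if (!pred(1)) return(NA_real_)
    lo <- 0; hi <- 1
    while (hi - lo > bisect_tol) {
      mid <- (lo + hi) / 2
      if (pred(mid)) hi <- mid else lo <- mid
    }
    hi
  }
  p0_b <- bisect(function(pr) jopt(pr) > 0)
  p_inf_b <- if (is.infinite(p_inf) || p_inf > 1) NA_real_ else {
    bisect(function(pr) is.infinite(jopt(pr)))
  }
  tibble::tibble(p0 = p0, p_inf = p_inf,
                 p0_bisect = p0_b, p_inf_bisect = p_inf_b)
}

#' Allocation policies
#'
#' Policies that map a display's probing probabilities to per-item mean
#' precisions:
#'
#' * `"rational"`: each item gets [optimal_resource()] at its relevance
#'   `r_i = u_i * p_i` (the per-item objective separates, so items are
#'   optimized independently).
#' * `"bays_fixed_total"`: minimizes the summed expected behavioral cost
#'   under the hard constraint `sum(J_i) = j_total` (optimal split of a
#'   fixed budget; water-filling on the marginal benefit).
#' * `"emrich_proportional"`: `J_i = p_i * j_total`.
#' * `"fixed_equal"`: `J_i = j_total / N`.
#' * `"power_law"`: `J_i = j1 * N^(-a)`, the descriptive power-law model.
#' * `"nonparametric"`: table lookup of `j_bar` by probing probability.
#'
#' @param kind Policy name.
#' @param j_total Total resource (bays / emrich / fixed kinds).
#' @param j1,a Power-law coefficients.
#' @param table For `"nonparametric"`: a data frame with columns `p_probe`
#'   and `j_bar`.
#' @return An object of class `allocation_policy`.
#' @export
#' @examples
#' allocation_policy("emrich_proportional", j_total = 8)
allocation_policy <- function(kind = c("rational", "bays_fixed_total",
                                       "emrich_proportional", "fixed_equal",
                                       "power_law", "nonparametric"),
                              j_total = NULL, j1 = NULL, a = NULL,
                              table = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("bays_fixed_total", "emrich_proportional", "fixed_equal")) {
    stopifnot(is.numeric(j_total), j_total >= 0)
  }
  if (kind == "power_law") stopifnot(is.numeric(j1), j1 >= 0, is.numeric(a))
  if (kind == "nonparametric") {
    stopifnot(is.data.frame(table), all(c("p_probe", "j_bar") %in% names(table)))
  }
  structure(list(kind = kind, j_total = j_total, j1 = j1, a = a,
                 table = table), class = "allocation_policy")
}

#' @export
print.allocation_policy <- function(x, ...) {
  cat("<allocation_policy>", x$kind, "\n")
  invisible(x)
}

# cbar and |cbar'| interpolators on a log-J grid; used by the constrained
# (fixed-total) solver and by the fast fitting path.
cbar_interp <- function(params, n_eps = 600, n_bins = .rrvwm$n_bins,
                        n_grid = 140) {
  s_grid <- seq(log(.rrvwm$j_lower), log(.rrvwm$j_upper), length.out = n_grid)
  j_grid <- exp(s_grid)
  cb <- expected_behavioral_cost(j_grid, params$tau, params$cost,
                                 n_eps = n_eps, n_bins = n_bins)
  cb0 <- expected_behavioral_cost(0, params$tau, params$cost,
                                  n_eps = n_eps, n_bins = n_bins)
  # cbar is non-increasing; clamp quadrature wiggles at extreme precisions
  cb <- cummin(cb)
  sp <- stats::splinefun(s_grid, cb, method = "monoH.FC")
  list(
    s_grid = s_grid, j_grid = j_grid, cb = cb, cb0 = cb0,
    cbar = function(j) ifelse(j <= .rrvwm$j_lower,
                              cb0 + (sp(s_grid[1]) - cb0) * j / .rrvwm$j_lower,
                              sp(pmin(log(j), s_grid[n_grid]))),
    # derivative wrt J (not log J)
    dcbar = function(j) sp(pmin(pmax(log(j), s_grid[1]), s_grid[n_grid]),
                           deriv = 1) / j
  )
}

# J_opt(p) on the interpolated objective; boundary at 0 included.
jopt_interp <- function(p, lambda, ci) {
  vapply(p, function(pi) {
    if (pi <= 0) return(0)
    if (lambda == 0) return(Inf)
    f <- pi * ci$cb + lambda * ci$j_grid
    k <- which.min(f)
    n <- length(ci$s_grid)
    if (k == n && f[n] < f[n - 1] && f[n] < pi * ci$cb0) return(Inf)
    lo <- ci$s_grid[max(1, k - 2)]; hi <- ci$s_grid[min(n, k + 2)]
    opt <- stats::optimize(function(s) pi * ci$cbar(exp(s)) + lambda * exp(s),
                           lower = lo, upper = hi, tol = 1e-8)
    if (pi * ci$cb0 <= opt$objective) 0 else exp(opt$minimum)
  }, numeric(1))
}

# water-filling solver: minimize sum(r_i cbar(J_i)) s.t. sum(J_i) = j_total
bays_allocate <- function(r, j_total, params, ci = NULL) {
  if (is.null(ci)) ci <- cbar_interp(params)
  n <- length(r)
  if (j_total <= 0 || all(r <= 0)) return(rep(0, n))
  # item i active iff r_i * |cbar'(0+)| > mu; J_i solves r_i * |cbar'(J)| = mu
  slope0 <- abs(ci$dcbar(.rrvwm$j_lower))
  j_of_mu <- function(mu) {
    vapply(r, function(ri) {
      if (ri <= 0 || ri * slope0 <= mu) return(0)
      g <- function(s) ri * abs(ci$dcbar(exp(s))) - mu
      lo <- ci$s_grid[1]; hi <- ci$s_grid[length(ci$s_grid)]
      if (g(hi) > 0) return(exp(hi))
      exp(stats::uniroot(g, lower = lo, upper = hi, tol = 1e-10)$root)
    }, numeric(1))
  }
  # bisect mu so the budget is met
  mu_hi <- max(r) * slope0
  mu_lo <- mu_hi * 1e-12
  for (it in 1:200) {
    mu <- sqrt(mu_lo * mu_hi)
    tot <- sum(j_of_mu(mu))
    if (abs(tot - j_total) < 1e-9 * max(1, j_total)) break
    if (tot > j_total) mu_lo <- mu else mu_hi <- mu
  }
  jj <- j_of_mu(mu)
  if (abs(sum(jj) - j_total) > 0.01 * max(1, j_total)) {
    stop("fixed-total allocation solver did not converge", call. = FALSE)
  }
  # rescale residual bisection error onto active items
  act <- jj > 0
  if (any(act)) jj[act] <- jj[act] * (j_total / sum(jj))
  jj
}

#' Allocate resource across a display
#'
#' Applies an [allocation_policy()] to a display described by its vector of
#' probing probabilities. Optional incentive weights `u_i` enter through the
#' item relevance `r_i = u_i * p_i` for the rational and fixed-total
#' policies.
#'
#' @param p Vector of probing probabilities in `[0, 1]`, one per item.
#' @param policy An [allocation_policy()].
#' @param params A [model_params()] (needed by the rational and fixed-total
#'   policies).
#' @param weights Optional non-negative incentive multipliers `u_i`
#'   (default 1).
#' @return Numeric vector of mean precisions `j_bar`, one per item.
#' @export
#' @examples
#' allocate_display(c(3 / 4, 1 / 4),
#'                  allocation_policy("emrich_proportional", j_total = 8))
allocate_display <- function(p, policy, params = NULL, weights = NULL) {
  stopifnot(inherits(policy, "allocation_policy"),
            is.numeric(p), all(p >= 0), all(p <= 1))
  n <- length(p)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0))
  r <- weights * p
  switch(policy$kind,
    rational = {
      stopifnot(inherits(params, "model_params"))
      ur <- unique(r)
      optimal_resource(ur, params)[match(r, ur)]
    },
    bays_fixed_total = {
      stopifnot(inherits(params, "model_params"))
      bays_allocate(r, policy$j_total, params)
    },
    emrich_proportional = p * policy$j_total,
    fixed_equal = rep(policy$j_total / n, n),
    power_law = rep(policy$j1 * n^(-policy$a), n),
    nonparametric = {
      idx <- vapply(p, function(pi) {
        hit <- which(abs(policy$table$p_probe - pi) < 1e-9)
        if (length(hit) == 0) {
          stop("no nonparametric table entry for p = ", pi, call. = FALSE)
        }
        hit[1]
      }, integer(1))
      policy$table$j_bar[idx]
    }
  )
}

#' Total invested resource across set sizes or probing probabilities
#'
#' For equal-probing displays (`p = 1/N`), the rational policy invests
#' `J_total(N) = N * J_opt(1/N)` in total; indexed by probing probability the
#' same quantity reads `J_total(p) = J_opt(p) / p`. The set size (or `p`) at
#' which the total peaks is the model's non-monotonicity signature.
#'
#' @param params A [model_params()].
#' @param set_sizes Integer vector of set sizes (used when `p_grid` is NULL).
#' @param p_grid Optional grid of probing probabilities in `(0, 1]`.
#' @param ... Passed to [optimal_resource()].
#' @return A tibble of class `total_resource_curve` with columns
#'   `set_size` or `p`, `j_item`, and `j_total`; the peak location is stored
#'   in attribute `peak` (and named `n_peak` / `p_peak`).
#' @export
#' @examples
#' \donttest{
#' crv <- total_resource_curve(model_params(lambda = 0.01, tau = 0))
#' attr(crv, "peak")
#' }
total_resource_curve <- function(params, set_sizes = 1:8, p_grid = NULL, ...) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(p_grid)) {
    j_item <- optimal_resource(1 / set_sizes, params, ...)
    out <- tibble::tibble(set_size = set_sizes, j_item = j_item,
                          j_total = set_sizes * j_item)
    peak <- c(n_peak = set_sizes[which.max(out$j_total)])
  } else {
    stopifnot(all(p_grid > 0), all(p_grid <= 1))
    j_item <- optimal_resource(p_grid, params, ...)
    out <- tibble::tibble(p = p_grid, j_item = j_item,
                          j_total = j_item / p_grid)
    peak <- c(p_peak = p_grid[which.max(out$j_total)])
  }
  attr(out, "peak") <- peak
  class(out) <- c("total_resource_curve", class(out))
  out
}

#' @export
autoplot.total_resource_curve <- function(object, ...) {
  xvar <- if ("set_size" %in% names(object)) "set_size" else "p"
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("j_item", "j_total"),
                            names_to = "quantity", values_to = "j")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$j,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = if (xvar == "set_size") "set size N" else
                    "probing probability p",
                  y = "mean precision (Fisher information)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
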