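# cache of common-random-number draws keyed by (seed, samples, items)
.cd_cache <- new.env(parent = emptyenv())

#' Change-detection task configuration
#'
#' Whole-display change detection: the observer sees two displays of
#' `n_items` items and reports whether any item changed. A change is present
#' on exactly half of the trials and is equally likely to affect each item.
#' The expected behavioral cost is the Bayesian observer's error probability,
#' estimated by Monte Carlo with common random numbers (the same underlying
#' draws are reused for every candidate allocation, which makes the
#' optimization surface smooth and the whole analysis deterministic given
#' `seed`).
#'
#' @param n_items Set size.
#' @param reward Reward per correct trial; it multiplies the error
#'   probability in the objective `reward * p_error + lambda * sum(J)`, so
#'   only the ratio `reward / lambda` matters.
#' @param lambda Neural-cost weight.
#' @param mc_samples Monte Carlo trials (default 2e5, giving a standard
#'   error of about 0.001 on the error probability).
#' @param seed Seed for the common random numbers.
#' @return A list of class `cd_config`.
#' @export
#' @examples
#' cd_config(n_items = 2, reward = 0.2)
cd_config <- function(n_items = 2, reward = 0.2, lambda = 0.01,
                      mc_samples = 2e5, seed = 1L) {
  stopifnot(n_items >= 1, reward >= 0, lambda >= 0, mc_samples >= 1000)
  structure(list(n_items = as.integer(n_items), reward = reward,
                 lambda = lambda, mc_samples = as.integer(mc_samples),
                 seed = as.integer(seed)),
            class = "cd_config")
}

cd_draws <- function(config) {
  key <- paste(config$seed, config$mc_samples, config$n_items, sep = "_")
  if (!is.null(.cd_cache[[key]])) return(.cd_cache[[key]])
  set.seed(config$seed)
  m <- config$mc_samples
  n <- config$n_items
  u <- matrix(runif(m * n), m, n)
  m1 <- m %/% 2                          # no-change trials
  changed <- rep_len(seq_len(n), m - m1)  # change equally likely per item
  out <- list(u = u, m1 = m1, changed = changed)
  .cd_cache[[key]] <- out
  out
}

# Bessel ratio A1(k) = I1(k)/I0(k) and its inverse (Newton-refined)
bessel_a1 <- function(k) {
  ifelse(k > 500, 1 - 1 / (2 * k) - 1 / (8 * k^2),
         besselI(pmin(k, 500), 1, expon.scaled = TRUE) /
           besselI(pmin(k, 500), 0, expon.scaled = TRUE))
}
bessel_a1_inv <- function(r) {
  if (r <= 0) return(0)
  if (r >= 1) return(Inf)
  k <- if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
       else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
       else 1 / (r^3 - 4 * r^2 + 3 * r)
  for (i in 1:25) {
    a <- bessel_a1(k)
    dk <- (a - r) / (1 - a / k - a^2)
    k <- max(k - dk, k / 4)
    if (abs(dk) < 1e-12 * (1 + k)) break
  }
  k
}

# effective concentration of the measured between-display change: the
# difference of two independent VM(kappa) measurement errors, approximated
# by the VM matching its first circular moment, A1(k_eff) = A1(kappa)^2
kappa_effective <- function(kappa) {
  vapply(kappa, function(k) {
    if (k <= 0) 0 else bessel_a1_inv(bessel_a1(k)^2)
  }, numeric(1))
}

# Von Mises quantile by inverse-CDF interpolation (mean 0)
q_vm <- function(u, kappa, n_grid = 4097) {
  if (kappa < 1e-10) return(2 * pi * (u - 0.5))
  x <- seq(-pi, pi, length.out = n_grid)
  lognorm <- if (kappa > 500) {
    0.5 * log(2 * pi / kappa) + log1p(1 / (8 * kappa))
  } else {
    log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  }
  f <- exp(kappa * (cos(x) - 1) - lognorm)
  h <- x[2] - x[1]
  cdf <- c(0, cumsum((f[-1] + f[-n_grid]) / 2 * h))
  cdf <- cdf / cdf[n_grid]
  stats::approx(cdf, x, xout = u, ties = "ordered")$y
}

#' Error probability of the Bayesian change-detection observer
#'
#' Each display contributes an independent Von Mises measurement of every
#' item with the concentration mapped from that item's invested resource
#' `J_i`; the observer's evidence about item i is the measured
#' between-display change, whose no-change distribution is the difference of
#' the two measurement noises — approximated by the Von Mises matching its
#' first circular moment, `A1(kappa_eff) = A1(kappa(J_i))^2`. Under a change
#' of item j, that item's measured change is uniform (uniform change
#' magnitude plus noise) while the others follow the no-change
#' distribution. The two-display convolution matters structurally: it gives
#' the error probability a finite slope at zero resource, which is what
#' makes an encode-nothing regime possible at low reward. The optimal
#' rule with a 0.5 change prior reports "change" when the mean likelihood
#' ratio `(1/N) * sum_i [(1/2pi) / VM(delta_i; kappa_i)]` exceeds 1.
#' Unencoded items (`J_i = 0`) contribute a ratio of exactly 1 and carry no
#' evidence.
#'
#' @param j_bar Vector of per-item mean precisions (length `n_items`).
#' @param config A [cd_config()].
#' @return Monte Carlo estimate of the error probability.
#' @export
#' @examples
#' \donttest{
#' cd_p_error(c(5, 5), cd_config(n_items = 2, mc_samples = 2e4))
#' }
cd_p_error <- function(j_bar, config) {
  stopifnot(inherits(config, "cd_config"),
            length(j_bar) == config$n_items, all(j_bar >= 0),
            all(is.finite(j_bar)))
  dr <- cd_draws(config)
  m <- config$mc_samples
  n <- config$n_items
  kap <- kappa_effective(j_to_kappa(j_bar))
  # log I0s(k) = log(I0(k) e^-k), so that log[(1/2pi)/VM] = logI0s + k(1-cos d)
  logi0s <- vapply(kap, function(k) {
    if (k < 1e-12) 0 else if (k > 500) {
      -0.5 * log(2 * pi * k) + log1p(1 / (8 * k))
    } else {
      log(besselI(k, 0, expon.scaled = TRUE))
    }
  }, numeric(1))
  logw <- matrix(0, m, n)
  for (i in seq_len(n)) {
    if (kap[i] < 1e-12) next  # exactly zero evidence
    d <- q_vm(dr$u[, i], kap[i])
    lw <- logi0s[i] + kap[i] * (1 - cos(d))
    # changed trials where this item changed: measurement is uniform instead
    ch_rows <- dr$m1 + which(dr$changed == i)
    if (length(ch_rows)) {
      du <- 2 * pi * (dr$u[ch_rows, i] - 0.5)
      lw[ch_rows] <- logi0s[i] + kap[i] * (1 - cos(du))
    }
    logw[, i] <- lw
  }
  # report "change" iff logsumexp(logw) > log n
  mx <- logw[, 1]
  if (n > 1) for (i in 2:n) mx <- pmax(mx, logw[, i])
  s <- mx + log(rowSums(exp(logw - mx)))
  report_change <- s > log(n)
  idx_nc <- seq_len(dr$m1)
  err_nc <- mean(report_change[idx_nc])
  err_ch <- mean(!report_change[-idx_nc])
  0.5 * err_nc + 0.5 * err_ch
}

#' Jointly optimal allocation for change detection
#'
#' Minimizes `reward * p_error(J) + lambda * sum(J)`. At any set size the
#' search compares the structured candidates "encode K items with a common
#' resource J" for K = 0..N (the equal-nonzero reduction; at N = 2 it is
#' audited against an unconstrained grid in the tests), optimizing J by a
#' log-grid scan plus Brent refinement on the common-random-number surface.
#'
#' @param config A [cd_config()].
#' @param j_max Upper bound of the per-item search range.
#' @return A list of class `cd_allocation`: `j_bar` (full vector),
#'   `k_optimal`, `j_per_encoded`, `p_error`, `objective`, and the
#'   per-K table `by_k`.
#' @export
#' @examples
#' \donttest{
#' optimize_global(cd_config(n_items = 2, reward = 0.35, lambda = 0.01,
#'                           mc_samples = 2e4))
#' }
optimize_global <- function(config, j_max = 500) {
  stopifnot(inherits(config, "cd_config"))
  n <- config$n_items
  obj_k <- function(k, j) {
    jv <- c(rep(j, k), rep(0, n - k))
    config$reward * cd_p_error(jv, config) + config$lambda * k * j
  }
  rows <- list()
  rows[[1]] <- tibble::tibble(k = 0, j = 0,
                              objective = config$reward * 0.5)
  if (n >= 1) {
    jg <- exp(seq(log(0.05), log(j_max), length.out = 25))
    for (k in seq_len(n)) {
      vals <- vapply(jg, function(j) obj_k(k, j), numeric(1))
      b <- which.min(vals)
      lo <- log(jg[max(1, b - 1)]); hi <- log(jg[min(length(jg), b + 1)])
      op <- stats::optimize(function(s) obj_k(k, exp(s)), lower = lo,
                            upper = hi, tol = 1e-4)
      rows[[k + 1]] <- tibble::tibble(k = k, j = exp(op$minimum),
                                      objective = op$objective)
    }
  }
  by_k <- dplyr::bind_rows(rows)
  best <- by_k[which.min(by_k$objective), ]
  jv <- c(rep(best$j, best$k), rep(0, n - best$k))
  structure(list(
    j_bar = jv, k_optimal = as.integer(best$k),
    j_per_encoded = if (best$k > 0) best$j else NA_real_,
    p_error = cd_p_error(jv, config), objective = best$objective,
    by_k = by_k, config = config
  ), class = "cd_allocation")
}

#' @export
print.cd_allocation <- function(x, ...) {
  cat("<cd_allocation> N =", x$config$n_items,
      "reward =", x$config$reward, "| K_optimal =", x$k_optimal,
      "| J per encoded item =", round(x$j_per_encoded, 3),
      "| p(error) =", round(x$p_error, 4), "\n")
  invisible(x)
}

#' Sweep the change-detection regimes
#'
#' Re-optimizes the allocation over a grid of rewards (at fixed set size) or
#' a grid of set sizes (at fixed reward), returning the optimal number of
#' encoded items and the resource per encoded item at each point.
#'
#' @param config A [cd_config()]; its `reward` (or `n_items`) is replaced by
#'   the grid values.
#' @param reward_grid Increasing vector of rewards.
#' @param set_sizes Alternative sweep variable (used when `reward_grid` is
#'   NULL).
#' @return A tibble of class `cd_sweep`: one row per grid point with
#'   `k_optimal`, `j_per_encoded`, `p_error`, `objective`.
#' @export
regime_sweep <- function(config, reward_grid = NULL, set_sizes = NULL) {
  stopifnot(inherits(config, "cd_config"),
            !is.null(reward_grid) || !is.null(set_sizes))
  if (!is.null(reward_grid)) {
    stopifnot(!is.unsorted(reward_grid))
    out <- purrr::map_dfr(reward_grid, function(r) {
      cfg <- config; cfg$reward <- r
      g <- optimize_global(cfg)
      tibble::tibble(reward = r, n_items = cfg$n_items,
                     k_optimal = g$k_optimal,
                     j_per_encoded = g$j_per_encoded,
                     p_error = g$p_error, objective = g$objective)
    })
  } else {
    out <- purrr::map_dfr(set_sizes, function(n) {
      cfg <- cd_config(n_items = n, reward = config$reward,
                       lambda = config$lambda,
                       mc_samples = config$mc_samples, seed = config$seed)
      g <- optimize_global(cfg)
      tibble::tibble(reward = cfg$reward, n_items = n,
                     k_optimal = g$k_optimal,
                     j_per_encoded = g$j_per_encoded,
                     p_error = g$p_error, objective = g$objective)
    })
  }
  class(out) <- c("cd_sweep", class(out))
  out
}

#' @export
autoplot.cd_sweep <- function(object, ...) {
  xvar <- if (length(unique(object$reward)) > 1) "reward" else "n_items"
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("k_optimal", "j_per_encoded"),
                            names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]], y = .data$value)) +
    ggplot2::geom_step(data = ~ dplyr::filter(.x, .data$quantity == "k_optimal")) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$quantity == "j_per_encoded")) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~ quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = xvar, y = NULL) +
    ggplot2::theme_minimal()
}
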