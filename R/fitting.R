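#' Model specifications for fitting
#'
#' A model specification names the allocation policy that generated the data
#' and the behavioral cost family, and thereby determines the free
#' parameters:
#'
#' * `"rational"`: cost parameters (e.g. `beta`), `lambda`, `tau`.
#' * `"power_law"`: `j1`, `a` (with `j_bar = j1 * N^-a`), `tau` — the
#'   descriptive variable-precision power-law model.
#' * `"fixed_equal"`: `j_total`, `tau`.
#' * `"emrich_proportional"`: `j_total`, `tau`.
#' * `"bays_fixed_total"`: `j_total`, cost parameters, `tau` (optimal split
#'   of a fixed budget; requires display compositions, see `displays`).
#' * `"nonparametric"`: one `j_bar` per unique probing probability plus
#'   `tau`.
#'
#' @param kind Policy kind (see above).
#' @param cost A [cost_spec()]; used by `"rational"` and
#'   `"bays_fixed_total"`. For `"rational"` the power family's `beta` (or the
#'   saturating family's two parameters) is fitted; parameter-free families
#'   contribute no free parameters.
#' @param n_bins Gamma discretization bins for the likelihood.
#' @param displays Optional tibble with columns `condition_tag` and
#'   `p_items` (list-column of display probing probabilities); required to
#'   fit `"bays_fixed_total"` to unequal-probability designs.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("rational", cost_spec("power", beta = 2))
model_spec <- function(kind = c("rational", "power_law", "fixed_equal",
                                "emrich_proportional", "bays_fixed_total",
                                "nonparametric"),
                       cost = cost_spec("power", beta = 1),
                       n_bins = .rrvwm$n_bins, displays = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(cost, "cost_spec"))
  structure(list(kind = kind, cost = cost, n_bins = as.integer(n_bins),
                 displays = displays),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$kind, "\n")
  if (x$kind %in% c("rational", "bays_fixed_total")) print(x$cost)
  invisible(x)
}

check_trial_data <- function(data) {
  need <- c("set_size", "p_probe", "error_rad")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("trial data must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(data$set_size >= 1), all(data$p_probe > 0),
            all(data$p_probe <= 1))
  data
}

# free-parameter layout: names on the natural scale; all are fitted as logs
# except the power-law exponent `a`.
param_info <- function(model, data) {
  base <- switch(model$kind,
    rational = {
      cn <- switch(model$cost$family,
                   power = "beta",
                   saturating = c("cost_scale", "cost_shape"),
                   character(0))
      c(cn, "lambda", "tau")
    },
    power_law = c("j1", "a", "tau"),
    fixed_equal = c("j_total", "tau"),
    emrich_proportional = c("j_total", "tau"),
    bays_fixed_total = {
      cn <- switch(model$cost$family,
                   power = "beta",
                   saturating = c("cost_scale", "cost_shape"),
                   character(0))
      c("j_total", cn, "tau")
    },
    nonparametric = {
      ps <- sort(unique(data$p_probe))
      c(paste0("j_", signif(ps, 6)), "tau")
    }
  )
  log_scale <- !(base %in% "a")
  lower <- ifelse(base == "a", -3,
           ifelse(base == "beta", 1e-3,
           ifelse(base == "lambda", 1e-8,
           ifelse(base == "tau", 1e-4, 1e-6))))
  upper <- ifelse(base == "a", 5,
           ifelse(base == "beta", 20,
           ifelse(base == "lambda", 10,
           ifelse(base == "tau", 300, 1e6))))
  tibble::tibble(term = base, log_scale = log_scale,
                 lower = lower, upper = upper)
}

to_internal <- function(theta, info) {
  x <- as.numeric(theta)
  x[info$log_scale] <- log(x[info$log_scale])
  x
}
to_natural <- function(x, info) {
  th <- ifelse(info$log_scale, exp(x), x)
  names(th) <- info$term
  th
}

# substitute fitted cost parameters into the cost spec
cost_with <- function(cost, theta) {
  if (cost$family == "power" && "beta" %in% names(theta)) {
    cost$params[["beta"]] <- theta[["beta"]]
  }
  if (cost$family == "saturating" && "cost_scale" %in% names(theta)) {
    cost$params[["scale"]] <- theta[["cost_scale"]]
    cost$params[["shape"]] <- theta[["cost_shape"]]
  }
  cost
}

# mean precision of the probed item for every trial, given natural-scale theta
trial_j_bar <- function(data, model, theta, fit_opts) {
  switch(model$kind,
    rational = {
      pars <- model_params(lambda = theta[["lambda"]], tau = theta[["tau"]],
                           cost = cost_with(model$cost, theta))
      up <- unique(data$p_probe)
      ci <- cbar_interp(pars, n_eps = fit_opts$n_eps,
                        n_bins = model$n_bins, n_grid = fit_opts$n_grid)
      jo <- jopt_interp(up, pars$lambda, ci)
      jo[match(data$p_probe, up)]
    },
    power_law = theta[["j1"]] * data$set_size^(-theta[["a"]]),
    fixed_equal = theta[["j_total"]] / data$set_size,
    emrich_proportional = data$p_probe * theta[["j_total"]],
    bays_fixed_total = {
      pars <- model_params(lambda = 1, tau = theta[["tau"]],
                           cost = cost_with(model$cost, theta))
      ci <- cbar_interp(pars, n_eps = fit_opts$n_eps,
                        n_bins = model$n_bins, n_grid = fit_opts$n_grid)
      if (is.null(model$displays)) {
        # equal-probability displays: optimal split of the budget is equal
        theta[["j_total"]] / data$set_size
      } else {
        key <- unique(data$condition_tag)
        jmap <- lapply(key, function(k) {
          pv <- model$displays$p_items[[match(k, model$displays$condition_tag)]]
          jj <- bays_allocate(pv, theta[["j_total"]], pars, ci = ci)
          stats::setNames(jj, signif(pv, 9))
        })
        names(jmap) <- key
        vapply(seq_len(nrow(data)), function(i) {
          jmap[[data$condition_tag[i]]][[as.character(signif(data$p_probe[i], 9))]]
        }, numeric(1))
      }
    },
    nonparametric = {
      ps <- sort(unique(data$p_probe))
      jv <- theta[paste0("j_", signif(ps, 6))]
      jv[match(data$p_probe, ps)]
    }
  )
}

#' Per-trial log likelihood
#'
#' Log of the predicted error density for each trial under a model
#' specification with parameters `theta`. The probed item's mean precision is
#' resolved through the model's allocation policy, and the density is the
#' gamma mixture of Von Mises components ([predicted_error_pdf()]); a floor
#' of `1e-10` guards degenerate allocations against `log(0)`.
#'
#' @param data Trial tibble with columns `set_size`, `p_probe`, `error_rad`
#'   (and `condition_tag` where the model needs display composition).
#' @param model A [model_spec()].
#' @param theta Named numeric vector of natural-scale parameters (see
#'   [model_spec()] for the layout).
#' @return Numeric vector of per-trial log likelihoods.
#' @export
#' @examples
#' d <- tibble::tibble(set_size = 2, p_probe = 0.5, error_rad = 0.3)
#' trial_loglik(d, model_spec("fixed_equal"), c(j_total = 8, tau = 2))
trial_loglik <- function(data, model, theta) {
  check_trial_data(data)
  stopifnot(inherits(model, "model_spec"))
  fit_opts <- fit_control()
  jb <- trial_j_bar(data, model, theta, fit_opts)
  tau <- theta[["tau"]]
  out <- numeric(nrow(data))
  for (j in unique(jb)) {
    idx <- which(jb == j)
    dens <- if (!is.finite(j)) {
      rep(.rrvwm$density_floor, length(idx))
    } else {
      cpp_mixture_pdf(data$error_rad[idx], j, tau, model$n_bins,
                      .rrvwm$tau_floor)
    }
    out[idx] <- log(pmax(dens, .rrvwm$density_floor))
  }
  out
}

#' Fitting controls
#'
#' Numerical settings of the maximum-likelihood machinery: resolution of the
#' expected-cost interpolant rebuilt at every likelihood evaluation
#' (`n_eps` quadrature points, `n_grid` log-spaced precisions), the number of
#' local searches started from the best coarse-grid points (`n_starts`), and
#' the Nelder-Mead budget.
#'
#' @param n_eps,n_grid Expected-cost interpolant resolution.
#' @param n_starts Local searches from the best grid points.
#' @param maxit,reltol Nelder-Mead settings.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_eps = 320, n_grid = 60, n_starts = 2,
                        maxit = 250, reltol = 1e-5) {
  structure(list(n_eps = n_eps, n_grid = n_grid, n_starts = n_starts,
                 maxit = maxit, reltol = reltol), class = "fit_control")
}

# coarse grid of natural-scale starting points, kind-specific
start_grid <- function(model, data, info) {
  gl <- function(lo, hi, n) exp(seq(log(lo), log(hi), length.out = n))
  grids <- switch(model$kind,
    rational = {
      g <- list(lambda = gl(1e-5, 0.3, 5), tau = c(1e-3, 1, 8, 40))
      if (model$cost$family == "power") g <- c(list(beta = gl(0.02, 4, 4)), g)
      if (model$cost$family == "saturating") {
        g <- c(list(cost_scale = gl(0.1, 2, 3), cost_shape = gl(0.5, 4, 3)), g)
      }
      g
    },
    power_law = list(j1 = gl(0.5, 100, 5), a = c(0, 0.5, 1, 1.5),
                     tau = c(1e-3, 1, 10, 60)),
    fixed_equal = list(j_total = gl(0.5, 200, 8), tau = c(1e-3, 1, 10, 60)),
    emrich_proportional = list(j_total = gl(0.5, 200, 8),
                               tau = c(1e-3, 1, 10, 60)),
    bays_fixed_total = {
      g <- list(j_total = gl(0.5, 200, 6), tau = c(1e-3, 1, 10, 60))
      if (model$cost$family == "power") g <- c(g, list(beta = c(0.2, 1, 3)))
      g
    },
    nonparametric = {
      # moment-based precision estimates per condition, scaled up and down
      ps <- sort(unique(data$p_probe))
      jhat <- vapply(ps, function(pp) {
        e <- data$error_rad[data$p_probe == pp]
        r <- sqrt(mean(cos(e))^2 + mean(sin(e))^2)
        kap <- a1inv(min(r, 0.999))
        max(kappa_to_j(kap), 1e-4)
      }, numeric(1))
      out <- lapply(c(0.5, 1, 2), function(s) {
        lapply(c(1e-3, 1, 10, 40), function(tv) {
          stats::setNames(c(jhat * s, tv), info$term)
        })
      })
      return(unlist(out, recursive = FALSE))
    }
  )
  eg <- do.call(expand.grid, grids)
  eg <- eg[, info$term, drop = FALSE]  # order as in the layout
  lapply(seq_len(nrow(eg)), function(i) {
    stats::setNames(as.numeric(eg[i, ]), info$term)
  })
}

# inverse of the Bessel ratio A1(kappa) = I1/I0 (Fisher's approximation)
a1inv <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

nll_factory <- function(data, model, info, fit_opts) {
  lo <- to_internal(info$lower, info); hi <- to_internal(info$upper, info)
  function(x) {
    pen <- sum(pmax(0, x - hi)^2 + pmax(0, lo - x)^2) * 1e4
    xc <- pmin(pmax(x, lo), hi)
    theta <- to_natural(xc, info)
    ll <- sum(trial_loglik_opts(data, model, theta, fit_opts))
    if (!is.finite(ll)) return(1e10)
    -ll + pen
  }
}

# internal variant of trial_loglik that honours fit options
trial_loglik_opts <- function(data, model, theta, fit_opts) {
  jb <- trial_j_bar(data, model, theta, fit_opts)
  tau <- theta[["tau"]]
  out <- numeric(nrow(data))
  for (j in unique(jb)) {
    idx <- which(jb == j)
    dens <- if (!is.finite(j)) {
      rep(.rrvwm$density_floor, length(idx))
    } else {
      cpp_mixture_pdf(data$error_rad[idx], j, tau, model$n_bins,
                      .rrvwm$tau_floor)
    }
    out[idx] <- log(pmax(dens, .rrvwm$density_floor))
  }
  out
}

#' Maximum-likelihood fit of a model to one subject's trials
#'
#' Maximizes the summed log likelihood over the model's free parameters.
#' Initial estimates come from a coarse grid over a wide range of parameter
#' values; Nelder-Mead simplex searches (in log space, which enforces
#' positivity) are started from the best grid points and the best local
#' optimum is returned. The procedure is deterministic given `seed`.
#'
#' @inheritParams trial_loglik
#' @param seed Integer seed (recorded; the search itself is deterministic).
#' @param control A [fit_control()].
#' @param starts Optional list of natural-scale named starting vectors; when
#'   supplied the coarse grid is skipped (used e.g. for warm-started
#'   cross-validation refits).
#' @return An object of class `vwm_fit` with elements `model`, `theta`
#'   (natural scale), `loglik`, `n_params`, `aic`, `cv_loglik` (`NA` until
#'   [crossval_5fold()] fills it), `n_trials`, `seed` and optimizer
#'   diagnostics. Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' \donttest{
#' d <- generate_trials(builtin_design("E1"),
#'                      allocation_policy("fixed_equal", j_total = 20),
#'                      model_params(0.01, 2), n_per_condition = 50, seed = 1)
#' fit_mle(d, model_spec("fixed_equal"), seed = 1)
#' }
fit_mle <- function(data, model, seed = 1L, control = fit_control(),
                    starts = NULL) {
  check_trial_data(data)
  stopifnot(inherits(model, "model_spec"), nrow(data) >= 1)
  set.seed(seed)
  info <- param_info(model, data)
  nll <- nll_factory(data, model, info, control)

  if (is.null(starts)) {
    cand <- start_grid(model, data, info)
    vals <- vapply(cand, function(th) nll(to_internal(th, info)), numeric(1))
    ord <- order(vals)
    starts <- cand[ord[seq_len(min(control$n_starts, length(cand)))]]
  }

  runs <- lapply(starts, function(th) {
    tryCatch(
      stats::optim(to_internal(th, info), nll, method = "Nelder-Mead",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL
    )
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0) {
    stop("all optimization starts failed for model '", model$kind, "'",
         call. = FALSE)
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  lo <- to_internal(info$lower, info); hi <- to_internal(info$upper, info)
  theta <- to_natural(pmin(pmax(best$par, lo), hi), info)
  loglik <- sum(trial_loglik_opts(data, model, theta, control))
  k <- nrow(info)
  structure(list(
    model = model, theta = theta, loglik = loglik, n_params = k,
    aic = 2 * k - 2 * loglik, cv_loglik = NA_real_, folds = NULL,
    n_trials = nrow(data), seed = seed, control = control,
    convergence = best$convergence,
    data_digest = c(n = nrow(data), s = sum(data$error_rad))
  ), class = "vwm_fit")
}

#' @export
print.vwm_fit <- function(x, ...) {
  cat("<vwm_fit>", x$model$kind, "| n =", x$n_trials,
      "| logLik =", round(x$loglik, 2), "| AIC =", round(x$aic, 2), "\n")
  print(round(x$theta, 5))
  invisible(x)
}

#' @export
tidy.vwm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @export
glance.vwm_fit <- function(x, ...) {
  tibble::tibble(kind = x$model$kind, n_params = x$n_params,
                 loglik = x$loglik, aic = x$aic, cv_loglik = x$cv_loglik,
                 n_trials = x$n_trials)
}

#' @export
autoplot.vwm_fit <- function(object, data = NULL, bins = 31, ...) {
  if (is.null(data)) stop("supply the fitted trial data via `data`",
                          call. = FALSE)
  grid <- seq(-pi, pi, length.out = 181)
  opts <- object$control
  conds <- dplyr::distinct(data, .data$set_size, .data$p_probe)
  pred <- purrr::pmap_dfr(conds, function(set_size, p_probe, ...) {
    row <- tibble::tibble(set_size = set_size, p_probe = p_probe,
                          error_rad = 0, condition_tag = "x")
    jb <- trial_j_bar(row, object$model, object$theta, opts)
    tibble::tibble(set_size = set_size, p_probe = p_probe, error_rad = grid,
                   density = cpp_mixture_pdf(grid, jb,
                                             object$theta[["tau"]],
                                             object$model$n_bins,
                                             .rrvwm$tau_floor))
  })
  ggplot2::ggplot(data, ggplot2::aes(x = .data$error_rad)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(y = .data$density), colour = "red") +
    ggplot2::facet_wrap(~ set_size + p_probe, labeller = "label_both") +
    ggplot2::labs(x = "estimation error (rad)", y = "density") +
    ggplot2::theme_minimal()
}

#' Interleaved five-fold cross-validation
#'
#' Splits trials by their 1-based row order: fold `k` holds out trials with
#' index congruent to `k` modulo 5 (fold 1 holds out trials 1, 6, 11, ...),
#' refits the model on the remaining 80%, and evaluates the held-out log
#' likelihood; `cv_loglik` is the sum over the five folds. Fold refits are
#' warm-started from the full-data maximum-likelihood estimate.
#'
#' @inheritParams fit_mle
#' @param fit Optional full-data [fit_mle()] result to reuse (otherwise it is
#'   computed first).
#' @return A `vwm_fit` with `cv_loglik` filled and a `folds` tibble
#'   (`fold`, `n_train`, `n_test`, `test_loglik`).
#' @export
crossval_5fold <- function(data, model, seed = 1L, control = fit_control(),
                           fit = NULL) {
  check_trial_data(data)
  if (nrow(data) < 5) stop("need at least 5 trials for 5-fold CV", call. = FALSE)
  if (is.null(fit)) fit <- fit_mle(data, model, seed = seed, control = control)
  idx <- seq_len(nrow(data))
  folds <- lapply(1:5, function(k) which(idx %% 5 == (k %% 5)))
  rows <- lapply(1:5, function(k) {
    test <- folds[[k]]
    train <- setdiff(idx, test)
    f <- fit_mle(data[train, , drop = FALSE], model, seed = seed,
                 control = control, starts = list(fit$theta))
    ll <- sum(trial_loglik_opts(data[test, , drop = FALSE], model, f$theta,
                                control))
    tibble::tibble(fold = k, n_train = length(train), n_test = length(test),
                   test_loglik = ll)
  })
  folds_tbl <- dplyr::bind_rows(rows)
  fit$folds <- folds_tbl
  fit$cv_loglik <- sum(folds_tbl$test_loglik)
  fit
}

#' Compare fitted models by AIC and cross-validated log likelihood
#'
#' Takes a named list of `vwm_fit` objects fitted to the same data and
#' reports, for each model, the difference to a reference model:
#' `delta_aic = aic(reference) - aic(model)` and
#' `delta_cv = cv_loglik(reference) - cv_loglik(model)`. With the
#' resource-rational model as reference, a negative `delta_aic` and a
#' positive `delta_cv` both indicate an advantage of the reference.
#'
#' @param fits Named list of `vwm_fit` objects on the same data.
#' @param reference Name of the reference model (default: first).
#' @return A tibble with one row per model.
#' @export
aic_compare <- function(fits, reference = names(fits)[1]) {
  stopifnot(is.list(fits), length(fits) >= 1, !is.null(names(fits)),
            reference %in% names(fits))
  dg <- lapply(fits, `[[`, "data_digest")
  if (length(unique(vapply(dg, paste, character(1), collapse = "/"))) != 1) {
    stop("all fits must be on the same data", call. = FALSE)
  }
  ref <- fits[[reference]]
  purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(
      model = nm, n_params = f$n_params, loglik = f$loglik, aic = f$aic,
      cv_loglik = f$cv_loglik,
      delta_aic = ref$aic - f$aic,
      delta_cv = ref$cv_loglik - f$cv_loglik
    )
  })
}

#' Summarize model comparisons across subjects
#'
#' Means and standard errors of the AIC and cross-validation differences
#' returned by [aic_compare()], across subjects.
#'
#' @param comparisons A tibble of stacked [aic_compare()] results with an
#'   added `subject` column.
#' @return A tibble with one row per model: mean and s.e.m. of `delta_aic`
#'   and `delta_cv`.
#' @export
compare_summary <- function(comparisons) {
  stopifnot(all(c("subject", "model", "delta_aic") %in% names(comparisons)))
  sem <- function(x) sd(x) / sqrt(length(x))
  comparisons |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      mean_delta_aic = mean(.data$delta_aic),
      sem_delta_aic = sem(.data$delta_aic),
      mean_delta_cv = mean(.data$delta_cv),
      sem_delta_cv = sem(.data$delta_cv),
      .groups = "drop"
    )
}
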