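test_that("per-trial log likelihood matches limits and an independent
          quadrature oracle", {
  d <- tibble::tibble(set_size = 2, p_probe = 0.5, error_rad = 0.4)
  # zero allocation: uniform density
  ll0 <- trial_loglik(d, model_spec("fixed_equal"),
                      c(j_total = 0, tau = 2))
  expect_equal(ll0, log(1 / (2 * pi)))

  # nonparametric: depends only on the table entry for the condition
  dd <- tibble::tibble(set_size = c(2, 2), p_probe = c(0.5, 0.5),
                       error_rad = c(0.1, 0.1))
  m_np <- model_spec("nonparametric")
  th <- c(8, 3); names(th) <- c("j_0.5", "tau")
  ll <- trial_loglik(dd, m_np, th)
  expect_equal(ll[1], ll[2])
  th2 <- th; th2[["j_0.5"]] <- 16
  expect_false(isTRUE(all.equal(trial_loglik(dd, m_np, th2)[1], ll[1])))

  # oracle: dense quadrature over the gamma (no equal-probability binning)
  set.seed(3)
  n <- 1000
  errs <- r_vm(n, j_to_kappa(rgamma(n, shape = 6 / 4, scale = 4)))
  dt <- tibble::tibble(set_size = 1, p_probe = 1, error_rad = errs)
  ll_pkg <- sum(trial_loglik(dt, model_spec("fixed_equal"),
                             c(j_total = 6, tau = 4)))
  ll_oracle <- sum(log(oracle_mixture_pdf(errs, 6, 4)))
  expect_lt(abs(ll_pkg - ll_oracle), 0.1)
})

test_that("fitted likelihoods are proper densities for every condition", {
  pars <- model_params(0.02, 10, cost_spec("power", beta = 1))
  d <- generate_trials(builtin_design("E1"), allocation_policy("rational"),
                       pars, n_per_condition = 40, seed = 5)
  f <- fit_mle(d, model_spec("fixed_equal"), seed = 1, control = quick_ctrl)
  for (n in unique(d$set_size)) {
    dens <- function(e) {
      exp(trial_loglik(tibble::tibble(set_size = n, p_probe = 1 / n,
                                      error_rad = e),
                       f$model, f$theta))
    }
    z <- integrate(Vectorize(dens), -pi, pi, rel.tol = 1e-8)$value
    expect_equal(z, 1, tolerance = 1e-4)
  }
})

test_that("maximum-likelihood fitting is deterministic and recovers a
          fixed-resource generator", {
  pars <- model_params(0, 3)
  d <- generate_trials(builtin_design("E1"),
                       allocation_policy("fixed_equal", j_total = 24),
                       pars, n_per_condition = 750, seed = 21)
  m <- model_spec("fixed_equal")
  f1 <- fit_mle(d, m, seed = 9, control = quick_ctrl)
  f2 <- fit_mle(d, m, seed = 9, control = quick_ctrl)
  expect_identical(f1$theta, f2$theta)
  expect_equal(f1$theta[["j_total"]], 24, tolerance = 0.10)
  expect_equal(f1$aic, 2 * f1$n_params - 2 * f1$loglik)
  expect_identical(f1$n_params, 2L)

  # broom-style accessors
  td <- tidy(f1)
  expect_identical(td$term, c("j_total", "tau"))
  gl <- glance(f1)
  expect_identical(gl$kind, "fixed_equal")
})

test_that("interleaved five-fold cross-validation splits trials by order", {
  pars <- model_params(0, 2)
  d <- generate_trials(builtin_design("E1"),
                       allocation_policy("fixed_equal", j_total = 15),
                       pars, n_per_condition = 10, seed = 2)
  m <- model_spec("fixed_equal")
  cvf <- crossval_5fold(d, m, seed = 1, control = quick_ctrl)
  expect_identical(nrow(cvf$folds), 5L)
  expect_identical(sum(cvf$folds$n_test), nrow(d))
  expect_equal(cvf$cv_loglik, sum(cvf$folds$test_loglik))
  # fold index arithmetic on a 10-trial set: fold 1 holds out trials 1 and 6
  idx <- 1:10
  expect_identical(which(idx %% 5 == 1), c(1L, 6L))
  expect_error(crossval_5fold(d[1:3, ], m), "at least 5")
})

test_that("AIC comparison table follows the reference-minus-model convention", {
  pars <- model_params(0, 3)
  d <- generate_trials(builtin_design("E1"),
                       allocation_policy("fixed_equal", j_total = 24),
                       pars, n_per_condition = 100, seed = 4)
  f_fix <- fit_mle(d, model_spec("fixed_equal"), seed = 1,
                   control = quick_ctrl)
  f_pow <- fit_mle(d, model_spec("power_law"), seed = 1, control = quick_ctrl)
  cmp <- aic_compare(list(fixed_equal = f_fix, fixed_equal2 = f_fix,
                          power_law = f_pow))
  expect_equal(cmp$delta_aic[cmp$model == "fixed_equal2"], 0)
  # fixed_equal is the generator: the extra power-law parameter should not
  # pay for itself
  expect_lt(cmp$delta_aic[cmp$model == "power_law"], 0)
  # mismatched data refused
  d2 <- d[1:300, ]
  f_other <- fit_mle(d2, model_spec("fixed_equal"), seed = 1,
                     control = quick_ctrl)
  expect_error(aic_compare(list(a = f_fix, b = f_other)), "same data")
})

test_that("a redundant extra parameter costs about two AIC points", {
  # fixed_equal data fitted by its own model vs the power law (which nests it
  # at a = 1): mean AIC penalty should be near 2
  pars <- model_params(0, 3)
  ctrl <- fit_control(n_eps = 250, n_grid = 45, n_starts = 3, maxit = 400,
                      reltol = 1e-7)
  dif <- vapply(1:12, function(sd) {
    d <- generate_trials(builtin_design("E1"),
                         allocation_policy("fixed_equal", j_total = 24),
                         pars, n_per_condition = 250, seed = 500 + sd)
    f1 <- fit_mle(d, model_spec("fixed_equal"), seed = 1, control = ctrl)
    f2 <- fit_mle(d, model_spec("power_law"), seed = 1, control = ctrl)
    f2$aic - f1$aic
  }, numeric(1))
  expect_gt(mean(dif), 0)
  expect_lt(mean(dif), 4)
})

test_that("nonparametric fit recovers the rational model's allocations", {
  pars <- model_params(0.0088, 7.4, cost_spec("power", beta = 0.61))
  d <- generate_trials(builtin_design("E1"), allocation_policy("rational"),
                       pars, n_per_condition = 900, seed = 31)
  f <- fit_mle(d, model_spec("nonparametric"), seed = 1, control = quick_ctrl)
  ps <- sort(unique(d$p_probe))
  j_true <- optimal_resource(ps, pars)
  j_hat <- f$theta[paste0("j_", signif(ps, 6))]
  expect_lt(median(abs(j_hat - j_true) / j_true), 0.15)
})
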