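test_that("per-item optimizer matches a brute-force scan and the regime logic", {
  pars <- model_params(0.01, 0)
  expect_identical(optimal_resource(0, pars), 0)

  # brute-force oracle on a dense log grid
  jg <- exp(seq(log(1e-6), log(1e5), length.out = 2e4))
  cb <- expected_behavioral_cost(jg, 0, cost_spec("squared"))
  f <- 0.25 * cb + 0.01 * jg
  j_brute <- jg[which.min(f)]
  expect_equal(optimal_resource(0.25, pars), j_brute, tolerance = 5e-3)

  # monotone in probing probability
  jo <- optimal_resource(c(0.125, 0.25, 0.5), pars)
  expect_true(all(diff(jo) > 0))

  # no neural cost: unbounded investment
  expect_identical(optimal_resource(0.3, model_params(0, 0)), Inf)

  # doubling lambda weakly decreases every optimum
  jo2 <- optimal_resource(c(0.125, 0.25, 0.5), model_params(0.02, 0))
  expect_true(all(jo2 <= jo + 1e-9))
})

test_that("probing-probability regimes: sweep structure and threshold
          cross-validation", {
  pars <- model_params(0.01, 20)
  th <- thresholds(pars)
  expect_gt(th$p0_bisect, 0)              # variable precision can give p0 > 0
  expect_lt(abs(th$p0 - th$p0_bisect), 1e-3)
  expect_gt(th$p_inf, 1)                  # no unbounded regime here

  # dense sweep: zero below p0, positive and increasing above
  ps <- seq(0.001, 1, length.out = 40)
  jo <- optimal_resource(ps, pars)
  below <- ps < th$p0_bisect - 1e-3
  above <- ps > th$p0_bisect + 1e-3
  expect_true(all(jo[below] == 0))
  expect_true(all(jo[above] > 0))
  expect_true(all(diff(jo[above]) > -1e-8))

  # lambda = 0 collapses all thresholds
  th0 <- thresholds(model_params(0, 5))
  expect_equal(th0$p0, 0)
  expect_equal(th0$p_inf, 0)
})

test_that("allocation policies implement their defining rules", {
  pars <- model_params(0.01, 0)
  # rational with equal probabilities gives equal allocations
  j_eq <- allocate_display(rep(1 / 4, 4), allocation_policy("rational"),
                           pars)
  expect_equal(j_eq, rep(j_eq[1], 4))
  # separability: matches the element-wise optimizer on r_i
  p <- c(3 / 4, 1 / 4)
  expect_equal(allocate_display(p, allocation_policy("rational"), pars),
               optimal_resource(p, pars))
  # incentive weights enter through r_i = u_i * p_i
  expect_equal(
    allocate_display(c(0.5, 0.5), allocation_policy("rational"), pars,
                     weights = c(1, 0.5)),
    optimal_resource(c(0.5, 0.25), pars))

  expect_equal(allocate_display(c(3 / 4, 1 / 4),
                                allocation_policy("emrich_proportional",
                                                  j_total = 8)),
               c(6, 2))
  expect_equal(allocate_display(rep(1 / 3, 3),
                                allocation_policy("fixed_equal",
                                                  j_total = 9)),
               rep(3, 3))
  expect_equal(allocate_display(rep(1 / 4, 4),
                                allocation_policy("power_law", j1 = 12,
                                                  a = 1)),
               rep(3, 4))
  tab <- tibble::tibble(p_probe = c(0.25, 0.75), j_bar = c(2, 9))
  expect_equal(allocate_display(c(0.75, 0.25),
                                allocation_policy("nonparametric",
                                                  table = tab)),
               c(9, 2))
  expect_error(allocate_display(0.5, allocation_policy("nonparametric",
                                                       table = tab)),
               "no nonparametric table entry")
})

test_that("fixed-total optimal split equalizes marginal benefit and matches
          the unconstrained optimum at its own total", {
  pars <- model_params(0.01, 0)
  # equal probabilities: budget split equally
  jb <- allocate_display(rep(1 / 2, 2),
                         allocation_policy("bays_fixed_total", j_total = 10),
                         pars)
  expect_equal(jb, c(5, 5), tolerance = 1e-6)

  # consistency: giving the constrained solver the rational policy's realized
  # total reproduces the rational per-item split
  p <- c(0.6, 0.3, 0.1)
  j_rat <- allocate_display(p, allocation_policy("rational"), pars)
  jb2 <- allocate_display(p, allocation_policy("bays_fixed_total",
                                               j_total = sum(j_rat)), pars)
  expect_equal(jb2, j_rat, tolerance = 0.01)

  # cross-check against a generic constrained optimizer (reparameterized on
  # the simplex)
  ci <- rrvwm:::cbar_interp(pars)
  obj <- function(x) {
    w <- exp(c(x, 0)); w <- w / sum(w) * 10
    sum(c(0.7, 0.3) * ci$cbar(w))
  }
  o <- optim(c(0, 0)[1], obj, method = "BFGS")
  w_opt <- exp(c(o$par, 0)); w_opt <- w_opt / sum(w_opt) * 10
  jb3 <- allocate_display(c(0.7, 0.3),
                          allocation_policy("bays_fixed_total", j_total = 10),
                          pars)
  expect_equal(jb3, w_opt, tolerance = 0.02)
})

test_that("total resource curves agree across parameterizations and peak
          interior at fitted-scale parameters", {
  pars <- model_params(0.0088, 7.4, cost_spec("power", beta = 0.61))
  crv_n <- total_resource_curve(pars, set_sizes = 1:12)
  crv_p <- total_resource_curve(pars, p_grid = 1 / (1:12))
  expect_equal(crv_n$j_total, crv_p$j_total, tolerance = 1e-9)
  pk <- attr(crv_n, "peak")[["n_peak"]]
  expect_gt(pk, 1)
  expect_lt(pk, 12)
  # proportional-allocation identity: if J_opt is linear in p the total is flat
  tab <- tibble::tibble(p_probe = 1 / (1:4), j_bar = 5 / (1:4))
  jt <- vapply(1:4, function(n) {
    n * allocate_display(1 / n, allocation_policy("nonparametric",
                                                  table = tab))
  }, numeric(1))
  expect_equal(jt, rep(5, 4))
})
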