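test_that("built-in designs encode the nine experimental structures", {
  e1 <- builtin_design("E1")
  expect_identical(e1$set_size, c(1L, 2L, 4L, 8L))
  expect_true(all(vapply(seq_len(nrow(e1)), function(i) {
    all(e1$p_items[[i]] == 1 / e1$set_size[i])
  }, logical(1))))

  e4 <- builtin_design("E4")
  expect_identical(e4$set_size, 1:8)

  e7 <- builtin_design("E7")
  expect_identical(e7$set_size, c(2L, 4L, 8L))
  expect_equal(e7$p_items[[1]], c(3 / 4, 1 / 4))
  expect_equal(e7$p_items[[2]], c(1 / 2, 1 / 6, 1 / 6, 1 / 6))
  expect_equal(e7$p_items[[3]], c(3 / 10, rep(1 / 10, 7)))
  expect_true(all(vapply(e7$p_items, sum, numeric(1)) - 1 < 1e-12))

  e8 <- builtin_design("E8")
  expect_setequal(vapply(e8$p_items, `[[`, numeric(1), 1),
                  c(1 / 6, 2 / 9, 1 / 4, 1 / 3, 1 / 2, 1))
  expect_true(all(e8$set_size == 4L))
  e9 <- builtin_design("E9")
  expect_setequal(vapply(e9$p_items, `[[`, numeric(1), 1),
                  c(1 / 12, 1 / 10, 2 / 15, 1 / 6, 1 / 3, 1 / 2, 1))
  expect_true(all(e9$set_size == 6L))

  expect_error(builtin_design("E10"), "unknown design")
})

test_that("generation is reproducible and respects the generative model", {
  pars <- model_params(0.01, 4)
  pol <- allocation_policy("fixed_equal", j_total = 12)
  d1 <- generate_trials(builtin_design("E2"), pol, pars,
                        n_per_condition = 60, seed = 99)
  d2 <- generate_trials(builtin_design("E2"), pol, pars,
                        n_per_condition = 60, seed = 99)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 240L)
  expect_true(all(abs(d1$p_probe - 1 / d1$set_size) < 1e-12))
  expect_true(all(d1$error_rad >= -pi & d1$error_rad < pi))

  # essentially noiseless encoding concentrates errors near zero
  d_hi <- generate_trials(builtin_design("E1"),
                          allocation_policy("fixed_equal", j_total = 4e5),
                          model_params(0.01, 0), n_per_condition = 250,
                          seed = 1)
  expect_lt(circ_variance(d_hi$error_rad), 0.01)
})

test_that("items never encoded produce uniform guessing errors", {
  # tau large enough that p0 exceeds the lowest probing probabilities
  pars <- model_params(0.03, 25, cost_spec("power", beta = 0.9))
  p0 <- thresholds(pars)$p0_bisect
  d <- generate_trials(builtin_design("E9"), allocation_policy("rational"),
                       pars, n_per_condition = 400, seed = 13)
  low <- d[d$p_probe < p0, ]
  expect_gt(nrow(low), 300)
  for (pp in unique(low$p_probe)) {
    expect_gt(ks_uniformity(low$error_rad[low$p_probe == pp]), 0.01)
  }
  # and probed high-relevance items are far from uniform
  hi <- d[d$p_probe == 1, ]
  expect_lt(ks_uniformity(hi$error_rad), 1e-6)
})

test_that("generated error histograms converge to the predicted density", {
  jb <- 7; tv <- 9
  d <- generate_trials(
    tibble::tibble(condition_tag = "c1", set_size = 1L, p_items = list(1)),
    allocation_policy("fixed_equal", j_total = jb),
    model_params(0.01, tv), n_per_condition = 1e5, seed = 8)
  br <- seq(-pi, pi, length.out = 61)
  emp <- hist(d$error_rad, breaks = br, plot = FALSE)$counts / nrow(d)
  mid <- (br[-1] + br[-61]) / 2
  thq <- predicted_error_pdf(mid, jb, tv) * diff(br)
  expect_lt(sum(abs(emp - thq / sum(thq))) / 2, 0.01)  # total variation
})

test_that("higher probing probability never receives less resource", {
  pars <- model_params(0.02, 8, cost_spec("power", beta = 1.2))
  for (nm in c("E7", "E8", "E9")) {
    des <- builtin_design(nm)
    for (i in seq_len(nrow(des))) {
      pv <- des$p_items[[i]]
      jv <- allocate_display(pv, allocation_policy("rational"), pars)
      o <- order(pv)
      expect_true(all(diff(jv[o]) >= -1e-9))
    }
  }
})

test_that("rational-policy data reproduce the set-size effect", {
  pars <- model_params(0.0088, 7.4, cost_spec("power", beta = 0.61))
  d <- generate_trials(builtin_design("E5"), allocation_policy("rational"),
                       pars, n_per_condition = 400, seed = 17)
  cv <- vapply(sort(unique(d$set_size)), function(n) {
    circ_variance(d$error_rad[d$set_size == n])
  }, numeric(1))
  # circular variance widens with set size (allow small local inversions)
  expect_gt(cv[8] , cv[1])
  expect_true(cor(1:8, cv, method = "spearman") > 0.8)
})

test_that("the recovery harness reports a deterministic confusion table", {
  models <- list(fixed_equal = model_spec("fixed_equal"),
                 emrich_proportional = model_spec("emrich_proportional"))
  out1 <- recovery_harness(builtin_design("E7"),
                           allocation_policy("emrich_proportional",
                                             j_total = 25),
                           model_params(0, 5), models, seeds = c(41, 42),
                           n_per_condition = 120, control = quick_ctrl,
                           true_theta = c(j_total = 25, tau = 5))
  out2 <- recovery_harness(builtin_design("E7"),
                           allocation_policy("emrich_proportional",
                                             j_total = 25),
                           model_params(0, 5), models, seeds = c(41, 42),
                           n_per_condition = 120, control = quick_ctrl,
                           true_theta = c(j_total = 25, tau = 5))
  expect_identical(out1$fits, out2$fits)
  # proportional generator wins on its own data
  w <- out1$fits[out1$fits$winner, ]
  expect_true(all(w$model == "emrich_proportional"))
  expect_true(all(out1$recovery$rel_error < 0.5))
})
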