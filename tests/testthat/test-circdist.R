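test_that("Fisher information and Von Mises concentration map into each other", {
  # kappa = 2 oracle: bisect kappa * I1/I0 computed straight from besselI
  f <- function(k) k * besselI(k, 1) / besselI(k, 0)
  j2 <- f(2)
  expect_equal(kappa_to_j(2), j2, tolerance = 1e-12)
  expect_equal(j_to_kappa(j2), 2, tolerance = 1e-8)
  expect_equal(j_to_kappa(1.3955), 2, tolerance = 1e-3)

  expect_identical(j_to_kappa(0), 0)
  expect_identical(kappa_to_j(0), 0)

  kgrid <- c(10^seq(-4, 3, length.out = 40), 0)
  expect_equal(j_to_kappa(kappa_to_j(kgrid)), kgrid, tolerance = 1e-8)
  # strictly increasing
  expect_true(all(diff(kappa_to_j(sort(kgrid))) >= 0))

  expect_error(j_to_kappa(-1), "non-negative")
  expect_error(kappa_to_j(NaN), "finite")
})

test_that("Von Mises error density is normalized, uniform at J = 0, and has the
          Bessel-ratio cosine moment", {
  expect_equal(vm_error_pdf(c(-2, 0, 1, 3), 0), rep(1 / (2 * pi), 4))
  for (j in c(0.5, 3, 40)) {
    z <- integrate(function(e) vm_error_pdf(e, j), -pi, pi,
                   rel.tol = 1e-10)$value
    expect_equal(z, 1, tolerance = 1e-8)
  }
  j2 <- kappa_to_j(2)
  m <- integrate(function(e) cos(e) * vm_error_pdf(e, j2), -pi, pi,
                 rel.tol = 1e-10)$value
  expect_equal(m, besselI(2, 1) / besselI(2, 0), tolerance = 1e-8)
  expect_equal(m, 0.6978, tolerance = 1e-4)
})

test_that("equal-probability precision discretization has the right mass and mean", {
  d0 <- discretize_precision(5, tau = 0)
  expect_identical(nrow(d0), 1L)
  expect_equal(d0$j, 5)

  d <- discretize_precision(10, tau = 5, n_bins = 50)
  expect_identical(nrow(d), 50L)
  expect_equal(sum(d$mass), 1)
  # quadrature oracle for the mean of the discretized distribution
  expect_equal(sum(d$j * d$mass), 10, tolerance = 0.02)
  # variance grows with tau at fixed mean
  v <- vapply(c(0.5, 2, 8), function(tv) {
    dd <- discretize_precision(10, tv)
    sum(dd$mass * (dd$j - sum(dd$mass * dd$j))^2)
  }, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("predicted error density: limits, symmetry, normalization, bin count", {
  eps <- seq(-pi, pi - 1e-9, length.out = 101)
  expect_equal(predicted_error_pdf(eps, 0, 5), rep(1 / (2 * pi), 101))
  expect_equal(predicted_error_pdf(eps, 4, 1e-3), vm_error_pdf(eps, 4),
               tolerance = 1e-4)
  # symmetry in eps
  expect_equal(predicted_error_pdf(eps, 7, 3), predicted_error_pdf(-eps, 7, 3))
  # normalization across the (j_bar, tau) lattice
  for (jb in c(0, 0.5, 5, 50)) {
    for (tv in c(1e-3, 1, 10, 30)) {
      z <- integrate(function(e) predicted_error_pdf(e, jb, tv), -pi, pi,
                     rel.tol = 1e-9, subdivisions = 400)$value
      expect_equal(z, 1, tolerance = 1e-6)
    }
  }
  # 50 vs 500 bins barely moves the density (absolute scale for moderate
  # variability; relative scale once the gamma shape drops below 1, where the
  # top equal-probability bin dominates the peak density)
  d50 <- predicted_error_pdf(eps, 8, 3, n_bins = 50)
  d500 <- predicted_error_pdf(eps, 8, 3, n_bins = 500)
  expect_lt(max(abs(d50 - d500)), 1e-3)
  s50 <- predicted_error_pdf(eps, 8, 10, n_bins = 50)
  s500 <- predicted_error_pdf(eps, 8, 10, n_bins = 500)
  expect_lt(max(abs(s50 - s500) / pmax(s500, 1e-3)), 0.01)
})

test_that("precision variability raises error kurtosis at fixed mean precision", {
  set.seed(42)
  n <- 5e4
  draw <- function(tau) {
    j <- if (tau < 1e-6) rep(6, n) else rgamma(n, shape = 6 / tau, scale = tau)
    r_vm(n, j_to_kappa(j))
  }
  e0 <- draw(0); e20 <- draw(20)
  expect_gt(circ_kurtosis(e20), circ_kurtosis(e0) + 0.1)
  # pure Von Mises kurtosis is small next to the heavy-tailed mixture
  expect_gt(circ_kurtosis(e20), 2 * circ_kurtosis(e0))
  # rotation invariance
  expect_equal(circ_kurtosis(wrap_angle(e20 + 1.1)), circ_kurtosis(e20),
               tolerance = 1e-10)
})

test_that("circular variance has its textbook endpoints", {
  expect_equal(circ_variance(rep(0.7, 10)), 0)
  expect_equal(circ_variance(c(0, pi)), 1)
  set.seed(7)
  expect_equal(circ_variance(runif(1e6, -pi, pi)), 1, tolerance = 0.01)
  expect_error(circ_variance(numeric(0)))
  expect_error(circ_kurtosis(rep(1, 5)), "degenerate")
})

test_that("KS uniformity test is calibrated on uniform data and rejects
          concentrated data", {
  set.seed(11)
  pvals <- vapply(1:100, function(i) ks_uniformity(runif(500, -pi, pi)),
                  numeric(1))
  expect_gte(mean(pvals > 0.05), 0.90)
  set.seed(12)
  expect_lt(ks_uniformity(r_vm(500, rep(5, 500))), 1e-3)
  expect_lt(ks_uniformity(rep(0.3, 100)), 1e-10)
})

test_that("angles wrap into [-pi, pi)", {
  expect_equal(wrap_angle(3 * pi), -pi)
  expect_equal(wrap_angle(c(0.2, -0.2)), c(0.2, -0.2))
  x <- seq(-20, 20, length.out = 200)
  w <- wrap_angle(x)
  expect_true(all(w >= -pi & w < pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
})
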