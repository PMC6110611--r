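# lightweight fitting controls for unit tests (acceptance tests use defaults
# unless stated otherwise in the block)
quick_ctrl <- fit_control(n_eps = 250, n_grid = 45, n_starts = 1, maxit = 150)

# independent mixture density oracle: integrate VM(e; J) against the gamma
# over J by trapezoid on a dense grid (no equal-probability binning)
oracle_mixture_pdf <- function(eps, j_bar, tau, n_j = 1e4) {
  if (j_bar == 0) return(rep(1 / (2 * pi), length(eps)))
  shape <- j_bar / tau
  qs <- qgamma(c(1e-7, 1 - 1e-7), shape = shape, scale = tau)
  jg <- seq(max(qs[1], 1e-12), qs[2], length.out = n_j)
  w <- dgamma(jg, shape = shape, scale = tau)
  kg <- j_to_kappa(jg)
  dens <- vapply(eps, function(e) {
    f <- exp(kg * (cos(e) - 1)) /
      (2 * pi * besselI(pmin(kg, 700), 0, expon.scaled = TRUE))
    big <- kg > 700
    if (any(big)) f[big] <- exp(kg[big] * (cos(e) - 1)) *
        sqrt(kg[big] / (2 * pi)) / (1 + 1 / (8 * kg[big]))
    h <- jg[2] - jg[1]
    sum((f * w)[-1] + (f * w)[-n_j]) / 2 * h
  }, numeric(1))
  # renormalize for the truncated gamma tails
  dens / (sum(w[-1] + w[-n_j]) / 2 * (jg[2] - jg[1]))
}
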