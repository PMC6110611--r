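#' Wrap angles into the canonical interval
#'
#' Maps angles (radians) into `[-pi, pi)` by wrapping modulo `2*pi`.
#'
#' @param theta Numeric vector of angles in radians.
#' @return Numeric vector of the same length in `[-pi, pi)`.
#' @export
#' @examples
#' wrap_angle(c(0, 3 * pi, -3.5 * pi))
wrap_angle <- function(theta) {
  stopifnot(is.numeric(theta))
  ((theta + pi) %% (2 * pi)) - pi
}

#' Convert between Fisher information and Von Mises concentration
#'
#' Encoding precision is quantified as the Fisher information `J` carried by a
#' Von Mises error distribution. `J` and the concentration parameter `kappa`
#' are one-to-one related through `J = kappa * I1(kappa) / I0(kappa)`, where
#' `I0` and `I1` are modified Bessel functions of the first kind. The mapping
#' is strictly increasing on `[0, Inf)` with `J = 0` iff `kappa = 0`;
#' `j_to_kappa()` inverts it by safeguarded Newton iteration to near machine
#' precision.
#'
#' @param j Non-negative Fisher information values.
#' @param kappa Non-negative Von Mises concentrations.
#' @return Numeric vector: the corresponding `kappa` (for `j_to_kappa`) or
#'   `J` (for `kappa_to_j`).
#' @export
#' @examples
#' kappa_to_j(2)
#' j_to_kappa(kappa_to_j(2))
j_to_kappa <- function(j) {
  if (!is.numeric(j) || any(!is.finite(j)) || any(j < 0)) {
    stop("`j` must be finite and non-negative", call. = FALSE)
  }
  cpp_kappa_of_j(as.numeric(j))
}

#' @rdname j_to_kappa
#' @export
kappa_to_j <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa < 0)) {
    stop("`kappa` must be finite and non-negative", call. = FALSE)
  }
  cpp_j_of_kappa(as.numeric(kappa))
}

#' Von Mises error density parameterized by Fisher information
#'
#' Density of a zero-mean Von Mises distribution whose concentration is the
#' one mapped from Fisher information `j` (see [j_to_kappa()]). At `j = 0`
#' this is the circular uniform density `1 / (2 * pi)`.
#'
#' @param epsilon Errors in radians (wrapped internally).
#' @param j Scalar non-negative Fisher information.
#' @return Density values at `epsilon`.
#' @export
#' @examples
#' vm_error_pdf(0, j = 3)
#' vm_error_pdf(seq(-pi, pi, length.out = 5), j = 0)
vm_error_pdf <- function(epsilon, j) {
  stopifnot(length(j) == 1L)
  if (!is.finite(j) || j < 0) stop("`j` must be finite and non-negative", call. = FALSE)
  kappa <- cpp_kappa_of_j(j)
  e <- wrap_angle(epsilon)
  if (kappa > 500) {
    lognorm <- 0.5 * log(2 * pi / kappa) + log1p(1 / (8 * kappa))
  } else {
    lognorm <- log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
  }
  exp(kappa * (cos(e) - 1) - lognorm)
}

#' Discretize the precision distribution into equal-probability bins
#'
#' Trial-to-trial variability in precision is modelled as a gamma
#' distribution over `J` with mean `j_bar` and scale `tau` (shape
#' `j_bar / tau`); larger `tau` means more variability at a fixed mean, and
#' `tau -> 0` collapses to a point mass at `j_bar`. For numerical work the
#' distribution is discretized into `n_bins` equal-probability bins, each
#' represented by its central quantile (the quantile at `(i - 0.5) / n_bins`)
#' with mass `1 / n_bins`. Below a small `tau` floor the point-mass branch is
#' returned directly.
#'
#' @param j_bar Non-negative mean precision.
#' @param tau Non-negative variability (gamma scale).
#' @param n_bins Number of bins (default 50).
#' @return A tibble with columns `j` (bin center) and `mass`.
#' @export
#' @examples
#' discretize_precision(10, tau = 5)
#' discretize_precision(5, tau = 0)   # point mass
discretize_precision <- function(j_bar, tau, n_bins = .rrvwm$n_bins) {
  stopifnot(length(j_bar) == 1L, length(tau) == 1L,
            is.finite(j_bar), j_bar >= 0, is.finite(tau), tau >= 0, n_bins >= 1)
  centers <- cpp_gamma_bins(j_bar, tau, as.integer(n_bins), .rrvwm$tau_floor)
  tibble::tibble(j = centers, mass = 1 / length(centers))
}

#' Predicted estimation-error density under variable precision
#'
#' The predicted error distribution for an item encoded with mean precision
#' `j_bar` and variability `tau` is the gamma mixture of Von Mises densities
#' `p(eps) = integral VM(eps; J) Gamma(J; j_bar, tau) dJ`, evaluated by
#' discretizing the gamma into equal-probability bins and averaging the Von
#' Mises densities at the bin centers. `tau -> 0` recovers the single Von
#' Mises; `j_bar = 0` gives the circular uniform.
#'
#' @inheritParams discretize_precision
#' @param epsilon Errors in radians.
#' @return Density values at `epsilon`.
#' @export
#' @examples
#' predicted_error_pdf(0, j_bar = 4, tau = 2)
predicted_error_pdf <- function(epsilon, j_bar, tau, n_bins = .rrvwm$n_bins) {
  stopifnot(length(j_bar) == 1L, length(tau) == 1L,
            is.finite(j_bar), j_bar >= 0, is.finite(tau), tau >= 0)
  cpp_mixture_pdf(wrap_angle(as.numeric(epsilon)), j_bar, tau,
                  as.integer(n_bins), .rrvwm$tau_floor)
}

#' Draw Von Mises errors
#'
#' Samples zero-mean Von Mises variates by the Best-Fisher wrapped-Cauchy
#' rejection method, driven by R's RNG (so `set.seed()` gives reproducible
#' draws). `kappa` is recycled to length `n`; `kappa = 0` gives uniform draws.
#'
#' @param n Number of draws.
#' @param kappa Concentration(s), recycled to length `n`.
#' @return `n` angles in `[-pi, pi)`.
#' @export
#' @examples
#' set.seed(1)
#' r_vm(5, kappa = 4)
r_vm <- function(n, kappa) {
  stopifnot(n >= 0, is.numeric(kappa), all(is.finite(kappa)), all(kappa >= 0))
  if (n == 0) return(numeric(0))
  cpp_rvm(rep_len(as.numeric(kappa), n))
}

#' Circular summary statistics of estimation errors
#'
#' `circ_variance()` returns `1 - R1`, where `R1` is the mean resultant
#' length. `circ_kurtosis()` uses the Fisher convention
#' `(R2 * cos(mu2 - 2 * mu1) - R1^4) / (1 - R1)^2`, where `Rk` and `muk` are
#' the length and direction of the k-th trigonometric moment; it is signalled
#' as an error for degenerate samples with `R1 = 1`.
#'
#' @param errors Non-empty numeric vector of angles in radians.
#' @return A single number: circular variance in `[0, 1]`, or circular
#'   kurtosis.
#' @export
#' @examples
#' circ_variance(r_vm(100, kappa = 2))
circ_variance <- function(errors) {
  stopifnot(is.numeric(errors), length(errors) > 0)
  1 - sqrt(mean(cos(errors))^2 + mean(sin(errors))^2)
}

#' @rdname circ_variance
#' @export
circ_kurtosis <- function(errors) {
  stopifnot(is.numeric(errors), length(errors) > 0)
  c1 <- mean(cos(errors)); s1 <- mean(sin(errors))
  c2 <- mean(cos(2 * errors)); s2 <- mean(sin(2 * errors))
  r1 <- sqrt(c1^2 + s1^2); r2 <- sqrt(c2^2 + s2^2)
  if (1 - r1 < 1e-12) {
    stop("circular kurtosis is undefined for a degenerate sample (R1 = 1)",
         call. = FALSE)
  }
  mu1 <- atan2(s1, c1); mu2 <- atan2(s2, c2)
  (r2 * cos(mu2 - 2 * mu1) - r1^4) / (1 - r1)^2
}

#' Kolmogorov-Smirnov test of circular uniformity
#'
#' Two-sided KS test of the wrapped errors against the uniform distribution
#' on `[-pi, pi)`. Used to check whether responses to items that received no
#' encoding resource are indistinguishable from guessing.
#'
#' @param errors Non-empty numeric vector of angles in radians.
#' @return The KS p-value.
#' @export
#' @examples
#' ks_uniformity(runif(200, -pi, pi))
ks_uniformity <- function(errors) {
  stopifnot(is.numeric(errors), length(errors) > 0)
  suppressWarnings(
    stats::ks.test(wrap_angle(errors), "punif", min = -pi, max = pi)$p.value
  )
}
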