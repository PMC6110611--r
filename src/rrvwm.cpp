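#include <Rcpp.h>
using namespace Rcpp;

// Ratio I1(k)/I0(k) of modified Bessel functions, computed with the
// exponentially scaled forms; asymptotic series above k = 500 where the
// scaled Bessel calls lose nothing but cost time.
static double bessel_ratio(double k) {
  if (k <= 0.0) return 0.0;
  if (k > 500.0) {
    double ik = 1.0 / k;
    return 1.0 - 0.5 * ik - 0.125 * ik * ik - 0.125 * ik * ik * ik -
           (25.0 / 128.0) * ik * ik * ik * ik;
  }
  return R::bessel_i(k, 1.0, 2.0) / R::bessel_i(k, 0.0, 2.0);
}

static double j_of_kappa_scalar(double k) { return k * bessel_ratio(k); }

// Invert J = kappa * I1/I0 by safeguarded Newton iteration.
// The map is strictly increasing with kappa*A(kappa) >= kappa - 1/2,
// so the root is bracketed by [0, j + 1].
static double kappa_of_j_scalar(double j) {
  if (j <= 0.0) return 0.0;
  double lo = 0.0, hi = j + 1.0;
  double k = (j < 1.0) ? std::sqrt(2.0 * j) : j + 0.5;
  if (k <= lo || k >= hi) k = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double A = bessel_ratio(k);
    double f = k * A - j;
    if (f > 0.0) hi = k; else lo = k;
    double Ap = 1.0 - A / k - A * A;  // d/dk I1/I0
    double df = A + k * Ap;
    double kn = (df > 0.0) ? k - f / df : 0.5 * (lo + hi);
    if (!(kn > lo && kn < hi)) kn = 0.5 * (lo + hi);
    if (std::fabs(kn - k) <= 1e-13 * (1.0 + std::fabs(kn))) { k = kn; break; }
    k = kn;
  }
  return k;
}

// Lazily built lookup table kappa(J), uniform in log J, used by the hot
// quadrature paths. Linear interpolation on an 8192-point grid keeps the
// relative error below ~1e-7, far inside the quadrature tolerance; the
// exported j_to_kappa() always uses the exact Newton solve.
static std::vector<double> kap_tab;
static double tab_lo, tab_hi, tab_step;
static const int TAB_N = 8192;

static void init_kappa_table() {
  if (!kap_tab.empty()) return;
  tab_lo = std::log(1e-8);
  tab_hi = std::log(1e7);
  tab_step = (tab_hi - tab_lo) / (TAB_N - 1);
  kap_tab.resize(TAB_N);
  for (int i = 0; i < TAB_N; ++i)
    kap_tab[i] = kappa_of_j_scalar(std::exp(tab_lo + i * tab_step));
}

static double kappa_lookup(double j) {
  if (j <= 0.0) return 0.0;
  init_kappa_table();
  double lj = std::log(j);
  if (lj <= tab_lo) return std::sqrt(2.0 * j);   // kappa ~ sqrt(2J) as J -> 0
  if (lj >= tab_hi) return j + 0.5;              // kappa ~ J + 1/2 as J -> Inf
  double t = (lj - tab_lo) / tab_step;
  int i = (int)t;
  double w = t - i;
  if (i < 1 || i > TAB_N - 3) {
    return kap_tab[i] * (1.0 - w) + kap_tab[i + 1] * w;
  }
  // Catmull-Rom cubic through the four surrounding nodes; the mapping is
  // smooth in log J, so this is accurate to ~1e-12 relative
  double p0 = kap_tab[i - 1], p1 = kap_tab[i], p2 = kap_tab[i + 1],
         p3 = kap_tab[i + 2];
  return p1 + 0.5 * w * (p2 - p0 +
         w * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         w * (3.0 * (p1 - p2) + p3 - p0)));
}

// [[Rcpp::export]]
NumericVector cpp_j_of_kappa(NumericVector kappa) {
  int n = kappa.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = j_of_kappa_scalar(kappa[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_kappa_of_j(NumericVector j) {
  int n = j.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kappa_of_j_scalar(j[i]);
  return out;
}

// Equal-probability discretization of gamma(mean j_bar, scale tau):
// bin centers are the quantiles at (i - 0.5)/n_bins. Below the tau floor
// (or at extreme shape where the gamma is numerically degenerate) a single
// point mass at j_bar is used.
static std::vector<double> gamma_bin_centers(double j_bar, double tau,
                                             int n_bins, double tau_floor) {
  std::vector<double> centers;
  if (j_bar <= 0.0) { centers.push_back(0.0); return centers; }
  double shape = (tau > 0.0) ? j_bar / tau : R_PosInf;
  if (tau < tau_floor || shape > 1e8 || n_bins <= 1) {
    centers.push_back(j_bar);
    return centers;
  }
  centers.resize(n_bins);
  for (int b = 0; b < n_bins; ++b) {
    double q = (b + 0.5) / n_bins;
    centers[b] = R::qgamma(q, shape, tau, 1, 0);
  }
  return centers;
}

// [[Rcpp::export]]
NumericVector cpp_gamma_bins(double j_bar, double tau, int n_bins,
                             double tau_floor) {
  std::vector<double> c = gamma_bin_centers(j_bar, tau, n_bins, tau_floor);
  return NumericVector(c.begin(), c.end());
}

// Pointwise behavioral cost on |eps|. Families:
// 1 power |e|^beta, 2 abs, 3 squared, 4 -cos(e),
// 5 saturating 1 - exp(-(|e|/s)^q), 6 binary threshold.
static double cost_point(double ae, int family, const NumericVector& cpar) {
  switch (family) {
    case 1: return std::pow(ae, cpar[0]);
    case 2: return ae;
    case 3: return ae * ae;
    case 4: return -std::cos(ae);
    case 5: return 1.0 - std::exp(-std::pow(ae / cpar[0], cpar[1]));
    case 6: return (ae < cpar[0]) ? 0.0 : 1.0;
    default: stop("unknown cost family code");
  }
  return NA_REAL;
}

// Von Mises CDF mass on [-theta, theta] for mean 0, via Simpson quadrature
// of the stable density form exp(kappa*(cos e - 1)) / (2 pi I0s(kappa)).
static double vm_mass_within(double theta, double kappa) {
  if (theta <= 0.0) return 0.0;
  if (theta >= M_PI) return 1.0;
  if (kappa <= 0.0) return theta / M_PI;
  double i0s = (kappa > 500.0) ? 0.0 : R::bessel_i(kappa, 0.0, 2.0);
  int n = 400;  // Simpson panels on [0, theta]
  double h = theta / (2 * n);
  double acc = 0.0;
  for (int i = 0; i <= 2 * n; ++i) {
    double e = i * h;
    double f;
    if (kappa > 500.0) {
      // large-kappa: normal-like, use asymptotic I0s ~ 1/sqrt(2 pi k)
      f = std::exp(kappa * (std::cos(e) - 1.0)) * std::sqrt(kappa / (2.0 * M_PI));
      f /= (1.0 + 1.0 / (8.0 * kappa));
    } else {
      f = std::exp(kappa * (std::cos(e) - 1.0)) / (2.0 * M_PI * i0s);
    }
    double w = (i == 0 || i == 2 * n) ? 1.0 : ((i % 2) ? 4.0 : 2.0);
    acc += w * f;
  }
  double half = acc * h / 3.0;
  double m = 2.0 * half;
  if (m > 1.0) m = 1.0;
  return m;
}

// Expected behavioral cost cbar(j_bar; tau) for each j_bar, integrating the
// pointwise cost against the gamma-mixture-of-Von-Mises error density.
// Smooth families use composite trapezoid on [0, pi] doubled by symmetry;
// the binary-threshold family uses exact mixture CDF masses so that the
// discontinuity never meets the quadrature grid.
// [[Rcpp::export]]
NumericVector cpp_cbar(NumericVector j_bar, double tau, int family,
                       NumericVector cpar, int n_bins, int n_eps,
                       double tau_floor) {
  int m = j_bar.size();
  NumericVector out(m);

  if (family == 6) {
    double theta = cpar[0];
    for (int i = 0; i < m; ++i) {
      std::vector<double> centers =
          gamma_bin_centers(j_bar[i], tau, n_bins, tau_floor);
      double mass = 0.0;
      for (size_t b = 0; b < centers.size(); ++b)
        mass += vm_mass_within(theta, kappa_lookup(centers[b]));
      mass /= centers.size();
      out[i] = 1.0 - mass;
    }
    return out;
  }

  // shared eps grid, cost values and composite-Simpson weights on [0, pi]
  if (n_eps % 2 == 0) ++n_eps;  // Simpson needs an even panel count
  std::vector<double> eps(n_eps), ce(n_eps), cose(n_eps), wq(n_eps);
  double h = M_PI / (n_eps - 1);
  for (int g = 0; g < n_eps; ++g) {
    eps[g] = g * h;
    cose[g] = std::cos(eps[g]);
    ce[g] = cost_point(eps[g], family, cpar);
    wq[g] = (g == 0 || g == n_eps - 1) ? 1.0 : ((g % 2) ? 4.0 : 2.0);
    wq[g] *= h / 3.0;
  }

  for (int i = 0; i < m; ++i) {
    std::vector<double> centers =
        gamma_bin_centers(j_bar[i], tau, n_bins, tau_floor);
    int nb = centers.size();
    double total = 0.0;
    for (int b = 0; b < nb; ++b) {
      double kappa = kappa_lookup(centers[b]);
      double lognorm;
      if (kappa > 500.0) {
        lognorm = 0.5 * std::log(2.0 * M_PI / kappa) +
                  std::log1p(1.0 / (8.0 * kappa));
      } else {
        lognorm = std::log(2.0 * M_PI * R::bessel_i(kappa, 0.0, 2.0));
      }
      double acc = 0.0;
      for (int g = 0; g < n_eps; ++g) {
        double arg = kappa * (cose[g] - 1.0) - lognorm;
        if (arg < -45.0 && kappa > 0.0) break;  // arg decreases with eps
        acc += wq[g] * ce[g] * std::exp(arg);
      }
      total += 2.0 * acc;  // symmetry: double the [0, pi] integral
    }
    out[i] = total / nb;
  }
  return out;
}

// Gamma-mixture-of-Von-Mises density evaluated at a vector of errors.
// [[Rcpp::export]]
NumericVector cpp_mixture_pdf(NumericVector eps, double j_bar, double tau,
                              int n_bins, double tau_floor) {
  int n = eps.size();
  NumericVector out(n);
  std::vector<double> centers = gamma_bin_centers(j_bar, tau, n_bins, tau_floor);
  int nb = centers.size();
  std::vector<double> kap(nb), lognorm(nb);
  for (int b = 0; b < nb; ++b) {
    kap[b] = kappa_lookup(centers[b]);
    if (kap[b] > 500.0) {
      lognorm[b] = 0.5 * std::log(2.0 * M_PI / kap[b]) +
                   std::log1p(1.0 / (8.0 * kap[b]));
    } else {
      lognorm[b] = std::log(2.0 * M_PI * R::bessel_i(kap[b], 0.0, 2.0));
    }
  }
  for (int i = 0; i < n; ++i) {
    double c = std::cos(eps[i]);
    double acc = 0.0;
    for (int b = 0; b < nb; ++b) {
      double arg = kap[b] * (c - 1.0) - lognorm[b];
      if (arg > -60.0) acc += std::exp(arg);
    }
    out[i] = acc / nb;
  }
  return out;
}

// Von Mises sampler (mean 0), Best & Fisher (1979) wrapped-Cauchy rejection,
// driven by R's RNG so that set.seed() governs reproducibility.
// [[Rcpp::export]]
NumericVector cpp_rvm(NumericVector kappa) {
  int n = kappa.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double k = kappa[i];
    // below ~1e-5 the wrapped-Cauchy envelope parameters lose all precision
    // (rho ~ k/2 comes from a difference of order k^2); the distribution is
    // uniform to the same order, so sample uniformly there
    if (k < 1e-5) { out[i] = R::runif(-M_PI, M_PI); continue; }
    double tau = 1.0 + std::sqrt(1.0 + 4.0 * k * k);
    double rho = (tau - std::sqrt(2.0 * tau)) / (2.0 * k);
    double r = (1.0 + rho * rho) / (2.0 * rho);
    double theta = NA_REAL;
    for (int guard = 0; guard < 10000; ++guard) {
      double u1 = R::unif_rand();
      double z = std::cos(M_PI * u1);
      double f = (1.0 + r * z) / (r + z);
      double c = k * (r - f);
      double u2 = R::unif_rand();
      if (c * (2.0 - c) - u2 > 0.0 || std::log(c / u2) + 1.0 - c >= 0.0) {
        double u3 = R::unif_rand();
        theta = (u3 > 0.5 ? 1.0 : -1.0) * std::acos(f);
        break;
      }
    }
    if (!R_finite(theta)) stop("Von Mises sampler failed to accept");
    out[i] = theta;
  }
  return out;
}
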