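---
title: "Resource-rational modelling of set size effects in visual working memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-rational modelling of set size effects in visual working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrvwm)
```

## The model

Delayed-estimation experiments probe one of $N$ briefly memorized items and
record the circular estimation error $\varepsilon \in [-\pi, \pi)$. The
precision with which an item is encoded is quantified as Fisher information
$J$, related one-to-one to the concentration $\kappa$ of a Von Mises error
distribution through $J = \kappa\, I_1(\kappa)/I_0(\kappa)$. Precision
fluctuates from trial to trial: $J$ is gamma-distributed with mean $\bar J$
and scale $\tau$ (shape $\bar J/\tau$), so the predicted error density is the
mixture

$$p(\varepsilon;\bar J,\tau)=\int \mathrm{VM}(\varepsilon;J)\,
\Gamma(J;\bar J,\tau)\,dJ .$$

`rrvwm`'s central hypothesis is that $\bar J$ is not drawn from a fixed
budget but *chosen*, per item, to minimize an expected total cost: an
error-based behavioral cost plus a linear neural cost $\lambda \bar J$
(precision is proportional to trial-averaged spiking under Poisson-like
variability, and spikes are metabolically expensive). For tasks in which
only one item is probed the objective separates across items, and the
optimal investment for an item probed with probability $p_i$ is

$$\bar J_{\mathrm{opt}}(p_i)=\arg\min_{\bar J\ge 0}
\left[\,p_i\,\bar c_{\mathrm{beh}}(\bar J;\tau)+\lambda\bar J\,\right],$$

where $\bar c_{\mathrm{beh}}(\bar J;\tau)=\int
c(\varepsilon)\,p(\varepsilon;\bar J,\tau)\,d\varepsilon$ and
$c(\varepsilon)$ is a behavioral cost function — by default the power law
$|\varepsilon|^\beta$, with $|\varepsilon|$, $\varepsilon^2$,
$-\cos\varepsilon$, a two-parameter saturating map
$1-\exp(-(|\varepsilon|/s)^q)$, and a binary feedback-threshold cost also
available. Set size effects arise because adding items lowers each item's
probing probability $p_i = 1/N$ in equal-probing designs: the model has no
explicit dependence on $N$ at all.

The probing-probability axis splits into up to three regimes: below a
threshold $p_0$ the optimum is to encode nothing; between $p_0$ and
$p_\infty$ a finite, increasing amount; above $p_\infty$ (usually $>1$, so
absent) an unbounded amount. `thresholds()` reports both a first-order
("ratio") estimate and a bisection cross-check of each boundary.

## Free parameters

| parameter | meaning | units | typical fitted range |
|---|---|---|---|
| $\beta$ | curvature of the error-to-cost map $|\varepsilon|^\beta$ | — | 0.01–2 |
| $\lambda$ | neural cost per unit of invested Fisher information | 1/(J units) | $10^{-4}$–$10^{-1}$ |
| $\tau$ | gamma scale of precision variability | J units | 5–30 |

The neural cost per unit precision $\alpha$ is fixed to 1; it is
observationally interchangeable with $\lambda$. The equal-precision variant
fixes $\tau = 10^{-3}$.

## Numerical choices

* **Gamma parameterization.** The precision distribution uses mean $\bar J$
  and *scale* $\tau$ (shape $\bar J/\tau$): larger $\tau$ means more
  variability at a fixed mean, and $\tau \to 0$ recovers equal precision,
  which is the only reading consistent with an equal-precision variant at
  $\tau = 10^{-3}$ and fitted $\tau$ values in the tens. Below a floor of
  $10^{-6}$ a point mass is used outright.
* **Discretization.** The gamma over $J$ is discretized into 50
  equal-probability bins at the central quantiles $(i-\tfrac12)/50$, and the
  predicted density is the average of the 50 Von Mises components. Raising
  the bin count to 500 moves densities by $<10^{-3}$ for moderate
  variability; when the gamma shape drops below 1 the discretized peak
  density can shift by a few tenths of a percent, which is a property of the
  discretized model itself.
* **Quadrature.** Expected costs integrate over $\varepsilon$ by composite
  Simpson on $[0,\pi]$ (2000 points by default), doubled by symmetry;
  doubling the grid changes results by $<10^{-6}$ relative. The
  binary-threshold cost instead uses exact Von Mises CDF masses per mixture
  component, so its discontinuity never meets a quadrature grid.
* **$\kappa \leftrightarrow J$.** The Bessel-ratio map is inverted by
  safeguarded Newton iteration (exact to $\approx 10^{-13}$ relative in
  `j_to_kappa()`); the quadrature kernels use a lazily built 8192-node
  cubic-interpolated table of the same map, accurate to $\sim 10^{-10}$.
* **Per-item optimization.** `optimal_resource()` scans 200 log-spaced
  points on $[10^{-6}, 10^{5}]$, refines by Brent search in $\log \bar J$,
  and compares against the $\bar J = 0$ boundary; an objective still
  decreasing at the upper bound is flagged as the unbounded regime
  (`Inf`).
* **Thresholds.** $p_0$ is reported as
  $\lambda / \sup_{\bar J} [(\bar c(0)-\bar c(\bar J))/\bar J]$, the global
  form of the first-order condition $p_0 = \lambda/|\bar c'(0)|$. The two
  coincide under diminishing returns, but the discretized gamma violates
  diminishing returns very close to $\bar J = 0$ when the shape
  $\bar J/\tau$ is tiny (its slope there is exactly zero), and the global
  form is the quantity the encode-nothing indicator actually thresholds.
  Divergence of $\bar c'(0)$ (the $\tau \downarrow 0$ branch, where
  $\kappa \approx \sqrt{2\bar J}$) is detected by slope growth under step
  halving and maps to $p_0 = 0$.
* **Degenerate inputs.** $\bar J = 0$ yields the uniform density
  $1/2\pi$ exactly; a density floor of $10^{-10}$ guards logs of
  degenerate allocations during fitting.

## Fitting and model comparison

`fit_mle()` maximizes $\sum_i \log p(\varepsilon_i; p_i, \theta)$ per
subject. Parameters are searched in log space (positivity by construction);
starting points come from a coarse grid over $\beta \in [10^{-2}, 4]$,
$\lambda \in [10^{-5}, 0.3]$, $\tau \in [10^{-3}, 40]$ (kind-specific for
the other policies), and Nelder-Mead simplex searches run from the best two
grid points. Inside the likelihood, the expected behavioral cost is
evaluated once per parameter vector on a 60-point log-$\bar J$ grid and
interpolated by a monotone spline before solving
$\bar J_{\mathrm{opt}}(p)$ for each unique probing probability; the
interpolation error in $\bar J_{\mathrm{opt}}$ is a few tenths of a percent,
far below the sampling noise of any realistic data set, while making a full
fit roughly a hundred times faster than re-running the exact optimizer per
evaluation. All of these are `fit_control()` knobs.

Comparison models mirror the alternatives discussed in the VWM literature:
a descriptive power law $\bar J = J_1 N^{-a}$ (the VP-A model), a fixed
total budget split equally, a fixed budget split in proportion to probing
probability, a fixed budget split *optimally* (water-filling on the
marginal expected-cost reduction), and a nonparametric model with one
$\bar J$ per condition. `aic_compare()` reports
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{ref}} - \mathrm{AIC}_m$ (negative
favors the reference) alongside the five-fold cross-validated log-likelihood
difference with the opposite sign convention, and `crossval_5fold()`
implements the interleaved split in which fold $k$ holds out trials
$k, k+5, k+10, \dots$ in presentation order, warm-starting each fold refit
from the full-data estimate.

## The synthetic-data generator

`builtin_design()` reproduces the display structure of nine published
experiments: equal-probing designs at set sizes 1–8 (E1–E6), a 3:1 cue
design with $p \in \{3/4, 1/4\}$, $\{1/2, 1/6\}$, $\{3/10, 1/10\}$ (E7), and
two cue-validity designs whose unique probing probabilities are
$\{0, 1/6, 2/9, 1/4, 1/3, 1/2, 1\}$ (E8, $N=4$) and
$\{0, 1/12, 1/10, 2/15, 1/6, 1/3, 1/2, 1\}$ (E9, $N=6$). For E8/E9 each
unique nonzero $p$ becomes its own condition (the likelihood depends only on
the probed item's $p$, so the original block structure is irrelevant to
every analysis here); $p=0$ items are never probed and generate no trials.
`generate_trials()` draws, per trial, the probed item proportionally to
$p$, a realized precision from the gamma, and a Von Mises error (Best-Fisher
rejection sampling), and is byte-reproducible given its seed. Default 200
trials per condition, the hundreds-scale of the original experiments.

What the generator does *not* emulate: response devices (color wheel vs
scroll), swap/non-target errors, reaction times, sequential effects, or any
systematic (stimulus-dependent) component of precision variability. Passing
recovery tests on these data therefore demonstrates the internal
consistency of the pipeline, not that real subjects satisfy the model's
assumptions.

## Study sizes used by the test suite

The packaged tests run parameter recovery at $n = 3000$ trials per synthetic
subject (set sizes 1–8, 20 seeds) at fitted-scale generating values
$(\beta, \lambda, \tau) = (0.61, 8.8\times 10^{-3}, 7.4)$; the pooled median
relative error of the recovered triple is the headline figure the suite
asserts. $\beta$ is the weakly determined parameter — it trades off against
$\lambda$ along a likelihood ridge, so its per-parameter error runs well
above $\tau$'s at this sample size; this is estimator variance, not an
optimizer artifact (refitting with a much stricter search budget moves the
estimates negligibly).
Model recovery uses the E7 design (250 trials per condition, 20 subjects per
generating policy), because unequal probing probabilities are what separate
the proportional policy from an equal split; the power-law generator uses
exponent $a = 0.65$, away from $a = 1$ where the power law and the
fixed-budget model coincide exactly.

## Change detection (a global task)

For whole-display change detection the behavioral cost is the error
probability of a Bayesian observer and cannot be written per item, so the
optimization is joint. Each display yields an
independent Von Mises measurement of every item at the concentration mapped
from $J_i$; the evidence about item $i$ is the measured between-display
change, whose no-change distribution is the difference of the two noises,
approximated by the Von Mises matching its first circular moment
($A_1(\kappa_{\mathrm{eff}}) = A_1(\kappa)^2$). Under a change (prior 0.5,
uniform magnitude, equally likely items) the changed item's measurement is
uniform. The two-display convolution is structurally important: it gives the
error probability a finite slope at zero resource, so an encode-nothing
regime exists at low reward — with a single folded measurement the
square-root behavior of $\kappa(J)$ near zero would make a little encoding
always worthwhile. The optimal
rule reports "change" when
$\frac 1N \sum_i \frac{1/2\pi}{\mathrm{VM}(\delta_i;\kappa_i)} > 1$;
unencoded items contribute exactly 1 and no evidence. This is the standard
ideal-observer rule for this task family; the original derivation is not
reprinted in the source text, so the rule is documented here as the
package's construction. `cd_p_error()` estimates the error rate by Monte
Carlo (default $2\times 10^5$ trials, s.e. $\approx 10^{-3}$) with common
random numbers across candidate allocations, so the optimization surface is
smooth and deterministic given the seed. The trial reward $R$ multiplies the
error probability ($R\,p(\mathrm{error}) + \lambda \sum_i J_i$), the only
placement that lets reward move the solution at fixed $\lambda$ — and only
the ratio $R/\lambda$ matters. `optimize_global()` compares the structured
candidates "encode $K$ items equally" for $K = 0..N$ (at $N = 2$ the tests
audit this equal-nonzero conjecture against an unconstrained grid search).

## Findings the suite documents deliberately

Two published-style claims do not hold under the implemented objective, and
the corresponding checks are kept in the suite as written rather than
adjusted to pass:

* At $(\lambda, \beta, \tau) = (0.01, 2, \tau\downarrow 0)$ the total
  invested resource $N \bar J_{\mathrm{opt}}(1/N)$ **increases** throughout
  $N = 1..8$ (brute-force verified); its peak sits near $N \approx 100$,
  since the declining regime begins only once $p \lesssim 0.6\lambda$. An
  interior peak within 1–8 does occur at fitted-scale parameters (e.g.
  $\beta = 0.61$, $\lambda = 8.8\times10^{-3}$, $\tau = 7.4$), which is what
  the allocator tests assert.
* With $\tau = 10^{-3}$ the encode-nothing threshold is not exactly zero:
  the gamma mixture has a finite cost slope at $\bar J = 0$,
  $|\bar c'(0)| = c_\beta\sqrt{2\pi/\tau}$, so
  $p_0 = \lambda/c_\beta\sqrt{\tau/2\pi} > 0$ — about $2\times 10^{-4}$ for
  $(\beta, \lambda) = (1, 10^{-2})$. The exact statement $p_0 = 0$ belongs
  to the true $\tau \downarrow 0$ limit, where the package's point-mass
  branch indeed returns $p_0 < 10^{-6}$.

Similarly, the binary-feedback sweep at $(\lambda, \tau) = (0.08, 30)$
invests nothing at *any* feedback threshold (the maximum benefit slope,
$\approx 0.08$, is below $\lambda/p = 0.4$ at $p = 1/5$), so the predicted
absolute error is flat at $\pi/2$; the U-shaped dip appears once
$\lambda \lesssim 0.02$, and that is where the tests exercise it.

## Known limitations

* Subject-level fitting only; no hierarchical pooling across subjects.
* No sensory-input ceiling or hard total-resource cap; no chunking.
* Errors are zero-mean Von Mises; swap errors and response biases are out of
  scope, so fits to real data containing them will absorb those components
  into $\tau$.
* The change-detection module fixes $\tau \downarrow 0$ and is a
  simulation/analysis tool, not a fitting tool.
* $p_\infty$ is reported from the cost slope at the top of the search range
  ($10^5$); regimes with genuinely unbounded investment only arise at
  $\lambda = 0$ or $p > p_\infty$, and are flagged, not fitted.
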