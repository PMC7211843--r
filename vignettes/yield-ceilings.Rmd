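---
title: "Estimating crop yield ceilings from threshold exceedances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating crop yield ceilings from threshold exceedances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldcap)
library(dplyr)
```

## The question and the model

Average winter wheat yields in temperate commercial production sit around
8 t/ha and have been roughly flat for two decades. Whether yields *can*
go much higher — whether there is a finite ceiling under current
technology and climate — is a question about the upper tail of the yield
distribution, not about its mean. yieldcap addresses it with the
peaks-over-threshold machinery of extreme value theory.

Given a high threshold $t$, the excess $Y = X - t$ of a yield $X$ over
$t$, conditional on $X > t$, is approximately generalized Pareto (GPD):

$$P(X - t \le y \mid X > t) \approx H_{\gamma,\sigma}(y) =
  1 - \left(1 + \gamma y / \sigma\right)^{-1/\gamma},$$

with scale $\sigma > 0$ and shape $\gamma$; at $\gamma = 0$ this is the
exponential $1 - e^{-y/\sigma}$. The shape is the scientifically loaded
parameter: $\gamma < 0$ implies the excesses live on $[0, -\sigma/\gamma]$
and the yield distribution has a finite right endpoint

$$x^* = t - \sigma / \gamma,$$

the maximum attainable yield under the conditions that generated the
data. That endpoint — its point estimate, its uncertainty, and whether it
differs across regions or input-spending bands — is the quantity of
interest.

In practice the threshold is set through the effective sample size $k$:
$t_k$ is the $(k+1)$th highest observation and the fit uses the $k$
highest yields as excesses over $t_k$. For $\gamma > -1/2$ the ML
estimator $(\hat\gamma_k, \hat\sigma_k)$ is asymptotically normal with
covariance $V/k$, $V_{11} = (1+\gamma)^2$, $V_{12} = -(1+\gamma)$,
$V_{22} = 1 + (1+\gamma)^2$, giving Gaussian confidence intervals (at the
conventional 95% level the package uses $z = 1.96$, matching how such
intervals are printed). The endpoint estimator
$\hat x^*_k = t_k - \hat\sigma_k/\hat\gamma_k$ is itself asymptotically
normal with standard deviation
$(\hat\sigma_k/\hat\gamma_k^2)\sqrt{1 + 4\gamma + 5\gamma^2 + 2\gamma^3 +
2\gamma^4}\,/\sqrt{k}$, and its symmetric interval gets one correction:
since the true endpoint cannot lie below an observed yield, the lower
limit is raised to the sample maximum $t_0$ whenever the Gaussian bound
falls below it (`endpoint_ci()` flags when this truncation binds).

## The pipeline

The analysis sample is built from a farm-year panel in three steps, all
data-frame in, tibble out:

* `deflate_costs()` expresses input costs in base-year money via a
  user-supplied price index (plain ratio adjustment, applied once to raw
  records);
* `dedup_farm_max()` keeps, per farm, the maximum yield across the years
  it appears — high-yielding farms participate repeatedly, and keeping
  every year would duplicate them in the tail. Region and costs are
  carried from the retained year; a tie on the maximum keeps the earliest
  year, which makes the result order-invariant;
* `stratify_by_region()` / `stratify_by_spend()` label each farm with a
  stratum: macro-region (east / north / west England-and-Wales groupings
  of the ten NUTS1 names), or input-spending bands of as-equal-as-possible
  size ordered by deflated fertilizer-plus-crop-protection spend. With
  $n$ not divisible by the number of groups, the larger groups sit at the
  low-spend end; ties in spend are broken by farm identifier so the
  equal-size split is reproducible.

`run_analysis()` chains these with exceedance selection, the ML fit, the
intervals above, and — when stratified — a likelihood-ratio test of
stratum-specific $(\gamma_g, \sigma_g)$ against a single $(\gamma,
\sigma)$ shared across the strata's own excess sets
($\mathrm{df} = 2(G-1)$). The pooled model deliberately keeps each
stratum's own threshold: strata differ in level, and the question the
test asks is whether the *tail shape and scale* differ, not the
thresholds. The LR construction over per-stratum excesses is a design
choice of this package; published analyses of this kind state the test
but not its exact construction.

```{r example}
report <- run_analysis(synth_config(n_farms = 700, seed = 2024),
                       stratify = "region", k = 80)
report
```

## Choosing the effective sample size

Small $k$ gives noisy estimates, large $k$ lets non-extreme yields bias
the fit. `shape_trajectory()` refits at every $k$ in a range (default
15–400, the window worth inspecting at these sample sizes) and
`stability_region()` recommends the largest $k$ whose trailing `window`
(default 50) of shape estimates spans at most `tol` (default 0.05) shape
units. The defaults encode what "the curve has flattened" usually means
for samples of 1000–2000 farms; the choice of $k$ is ultimately visual,
so the heuristic returns its full rolling diagnostics, never overrides an
explicit `k`, and warns rather than fails when nothing stabilises.
`autoplot()` draws the shape and endpoint trajectories.

## The synthetic farm panel

Farm-level survey yields are not public, so the generator provides a
panel with the structure the analysis assumes and a *known* ceiling:

* a register of `n_farms` farms, each with a persistent Gaussian yield
  effect (sd `within_farm_sd`, 0.8 t/ha), a home region, and a log-normal
  input-spend level; each farm-year is observed with probability
  `participation_prob` (0.45, giving roughly 700 observed farms per year
  at the default register size over ten years, with repeated
  participation so the per-farm-maximum step is non-trivial);
* yields are a mixture: with probability `tail_prob` (0.04) an exceedance
  `tail_threshold + GPD(tail_gamma, tail_sigma)` — defaults 10.69 t/ha,
  $\gamma = -0.11$, $\sigma = 0.76$, so the true ceiling is
  `true_endpoint(cfg)` $= 17.599$ t/ha at zero regional shift — otherwise
  a normal bulk (mean 8, sd 1.6 t/ha) truncated to $[0, u]$;
* regional shifts (`region_effects`) translate both components, so each
  region's ceiling is exactly the shifted GPD bound; the farm effect and
  the spending effect (`input_effect` per sd of log spend) enter the
  *bulk only*. Perturbing the exceedances would move the tail off the
  nominal GPD and destroy the known ground truth, which is the
  generator's whole purpose; the cost is that spending and farm identity
  influence who gets *near* the tail but not the tail law itself.
* the global seed drives a register stream plus one sub-stream per farm,
  so `farm_records()` reproduces any single farm without regenerating the
  panel, and a fixed seed reproduces the panel byte-identically (yields
  are recorded to $10^{-8}$ t/ha, rounded down so the ceiling is never
  crossed by rounding; costs to the penny — this also makes CSV
  round-trips exact).

What the generator does **not** emulate: weather-driven year effects and
temporal trends, survey sampling weights, spatial correlation, or any
dependence of the tail law on spending. Tests passing on this panel show
the estimators recover a genuine GPD tail through the full pipeline; they
do not show that real wheat yields follow a GPD, which is the modelling
assumption the method rests on.

## Numerical choices

* ML runs on $(\gamma, \log\sigma)$ with Nelder–Mead, multi-started from
  the probability-weighted-moment estimate, the moment estimate, and
  $(0.1, \log \bar y)$; parameter points violating the support constraint
  $1 + \gamma y_i/\sigma > 0$ (or $|\gamma| > 5$) are penalised to
  $-\infty$, keeping the optimiser unconstrained. The likelihood is
  irregular near the support boundary, hence the restarts; the best
  converged solution wins.
* All four distribution functions switch to the exponential forms below
  $|\gamma| = 10^{-6}$, keeping everything continuous through
  $\gamma = 0$ (verified to $10^{-6}$ in the tests; the CDF/quantile
  round trip holds to $10^{-10}$ across $\gamma \in [-0.9, 0.9]$).
* Ties exactly at the threshold are an error, not a silent adjustment:
  the model needs exactly $k$ strictly positive excesses, and a tied
  $(k+1)$th value makes that impossible for the requested $k$.
* Fits with $\hat\gamma \le -1/2$ are returned but flagged: the ML
  asymptotics (and every Gaussian interval) are invalid there, so
  intervals are withheld.
* The endpoint-variance polynomial is evaluated in Horner form; the scale
  interval uses the same symmetric Gaussian recipe as the shape interval
  and is labelled as such (likelihood-based scale intervals would be
  asymmetric; published tables of this kind do not state their method).
* The profile-likelihood interval for a once-in-$m$ level
  reparameterises $(\gamma, \sigma) \to (\gamma, z_m)$, profiles
  $\gamma$ by Brent, and inverts the $\chi^2_1$ cutoff by bisection. At
  $m = \infty$ the level is the endpoint itself and the constraint
  becomes $\sigma = -\gamma(z - t_k)$ with $\gamma < 0$; in that limit
  the interval is, by construction, unbounded above exactly when the
  data cannot exclude $\gamma \ge 0$ — a tail with no finite endpoint.
  For finite $m$ the level is finite even under a heavy tail, so the
  interval is typically bounded. The search declares unboundedness after
  probing to ten times the point estimate's excess over the threshold.
  Note the approach to the endpoint is slow for mild shapes: at
  $\gamma = -0.11$ the once-in-$10^{12}$ level is still ~0.4 t/ha below
  the endpoint, so "the ceiling" and "a once-in-a-very-long-period
  level" are only interchangeable for strongly bounded tails.

## Display conventions

Reports round to 2 decimals, half away from zero, for display only; the
JSON written by `write_report()` always carries full-precision values
alongside the display strings, and nothing downstream ever computes from
a rounded number.

## Known limitations

* **Finite-$k$ interval coverage.** The package's own calibration
  simulation (in the test suite) draws 2000 exceedance sets at
  $\gamma = -0.2$, $\sigma = 1$, $k = 250$ and measures the coverage of
  the 95% intervals: the Gaussian shape interval covers ~87–88% and the
  truncated endpoint interval ~80%, with every endpoint miss on the
  "truth above the upper limit" side. This is not an implementation
  artefact — an independent ML implementation reproduces the same
  sampling spread, which simply exceeds the asymptotic formulas at this
  $k$ (the endpoint estimator inherits strong right skew through
  $1/\hat\gamma^2$). Coverage climbs towards nominal as $k$ grows
  (~91%/88% at $k = 1000$, ~94%/93% at $k = 4000$). Intervals at survey
  scale ($k$ of a few hundred) should therefore be read as optimistic,
  and the endpoint's upper uncertainty especially so.
* The GPD form of the tail is an assumption; the moment and PWM
  estimators (`fit_gpd_moment()`, `fit_gpd_pwm()`) are provided as
  robustness checks precisely because their validity does not rest on
  it. Estimates close to the ML fit are reassurance, not proof.
* The stability heuristic is an aid to a visual judgement, not an
  optimal-$k$ rule; report the trajectory alongside any automated
  choice.
* Covariate-dependent tail parameters (shape or scale varying smoothly
  with spending or location) are out of scope; strata are compared by
  likelihood ratio instead.

## Problem sizes used in validation

The shipped tests validate estimation at $k$ up to 5000 excesses (200
replicates for recovery), interval calibration at $k = 250$ (2000
replicates), LR test size with three strata of $k = 150$ (500
replicates), and exhaustive 200×200 grid-search cross-checks of the ML
optimum on 50 excess sets of 50–500 points — sizes chosen to pin each
property down with Monte-Carlo error well inside the asserted bands.
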