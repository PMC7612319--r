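---
title: "Value of Information methods in voikit: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Value of Information methods in voikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

voikit quantifies what further research on uncertain model inputs is
expected to be worth. This vignette is the package's account of the
science: the measures it computes, the estimators it uses, the worked
health impact model it ships, and the choices made where the design was
genuinely open.

## 1. The decision-theoretic frame

All computations start from a single Monte Carlo sample: an R × P table
of parameter draws θ⁽ʳ⁾ from their joint uncertainty distribution, and
the matching model outputs — a vector y⁽ʳ⁾ = f(θ⁽ʳ⁾) for estimation
problems, or an R × A table of net benefits NB_a(θ⁽ʳ⁾) for decisions
among A actions. The containers `parameter_draws()` and `output_draws()`
enforce alignment, completeness and (for decisions) at least two
actions; every estimator dispatches on the output kind.

**Decision problems.** The current decision maximizes expected net
benefit. EVPI is the mean of the per-draw opportunity benefit
max_a NB_a(θ⁽ʳ⁾) − NB_{a*}(θ⁽ʳ⁾), which is algebraically identical to
the two-term form E[max_a NB_a] − max_a E[NB_a]; the identity is
asserted in the tests to machine precision. A tie in expected net
benefit is broken toward the lowest action index, with a warning — the
choice does not affect the EVPI value, only which action is labelled
"current".

**Estimation problems.** Under squared-error loss the optimal report is
the mean and the expected loss is the variance, so VoI measures are
variance reductions: EVPI = var(Y), EVPPI_φ = var(Y) − E_φ[var(Y|φ)],
and EVSI likewise with the study data Z in place of φ. Absolute-error
loss (median / mean absolute deviation) is deliberately out of scope.
The empirical variance uses divisor R − 1; at the sample sizes where
these methods are reliable (thousands of draws) the divisor is
immaterial, and the unbiased form keeps small-sample identities exact
(e.g. var of (1,2,3,4) = 5/3).

Monte Carlo noise can push a VoI estimate slightly negative; estimates
are clipped to zero, flagged, and the raw value kept in `meta$raw`.
EVPI for decisions carries a standard error (SE of the opportunity
benefit mean); estimation EVPI a fourth-moment-based SE of the variance.

## 2. Regression emulation of EVPPI and EVSI

EVPPI and EVSI involve nested expectations, and brute-force two-level
Monte Carlo is prohibitively expensive in general. voikit instead fits
y⁽ʳ⁾ = h(φ⁽ʳ⁾) + ε⁽ʳ⁾ with a flexible mean h. Then

* estimator (a): var(ĥ(φ⁽ʳ⁾)) estimates var_φ(E[Y|φ]) = EVPPI_φ, and
* estimator (b): var(y) − σ̂² estimates the same thing through the law of
  total variance.

Estimator (a) is reported; (b) and their discrepancy travel in `meta` as
a built-in diagnostic — a large gap means the fit is under- or
over-smoothing. For decisions, one surface is fitted per action and
EVPPI = mean_r[max_a ĥ_a⁽ʳ⁾] − max_a[mean_r NB_a⁽ʳ⁾]; actions with
constant net benefit (like a status quo pinned at zero) are handled as
exact constants. EVSI is the same computation with the predictors
replaced by simulated study summaries T(Z⁽ʳ⁾), Z⁽ʳ⁾ ~ p(Z | θ⁽ʳ⁾); one
seed governs the simulation for each study size.

The residual variance is defined as the empirical variance of the
residuals (divisor R − 1), so var(y) ≈ var(fitted) + σ̂² holds up to the
small non-orthogonality of penalized fits; the tests require the
decomposition to close within 2%.

### Backends

* **`spline_gam`** — penalized cubic regression splines via `mgcv::gam`,
  smoothness chosen by GCV. One predictor: a single smooth with basis
  dimension min(10, ⌊R/50⌋) (capped by the number of distinct values);
  two predictors: a tensor-product smooth; three or four: additive
  smooths. A lone predictor with ≤ 5 distinct values (a small-count
  summary statistic such as a binomial Z with n = 2) is fitted by exact
  group means — which *is* the conditional mean estimator there.
* **`adaptive_splines`** — multivariate adaptive regression splines,
  implemented in the package: forward selection of reflected hinge pairs
  max(0, ±(x − t)) and their products (interaction degree ≤ 2, knots at
  up to 15 interior quantiles per predictor, candidate scoring by
  residual sum-of-squares reduction against an orthonormalized current
  basis), to at most 21 terms, then backward pruning by GCV with the
  conventional penalty of 3 effective parameters per term.
* **`gaussian_process`** — squared-exponential kernel with per-dimension
  lengthscales plus a nugget, hyperparameters by L-BFGS-B maximization
  of the marginal likelihood with analytic gradients, on standardized
  inputs and outputs. For tractability the process is trained on a
  random subset of min(R, 2000) draws (seeded, configurable via
  `gp_subset`) and the posterior mean is evaluated at all R draws. The
  GP's regularization shrinks fitted values slightly toward the mean, so
  its var(fitted) runs a few percent low on noisy problems — one reason
  the (a)/(b) diagnostic pair and cross-backend comparison exist.
* **`auto`** — fits all three on a seeded 80/20 train/validation split
  and refits the backend with the lowest held-out MSE on the full
  sample.

Default backend by dimension of φ: splines up to p = 4 (where additive
GAMs are known to perform adequately), adaptive splines for 5 ≤ p ≤ 15;
joint EVPPI beyond 15 parameters is refused rather than silently
extrapolated, since no regression method is reliable there. Reliable
surface identification needs draws to spare: over about 5000 draws are
advisable when several parameters are learned jointly.

Monte Carlo uncertainty of the regression-based estimates is reported as
a cheap plug-in SE (sampling noise of the fitted values; smoothing
uncertainty excluded) or, with `nboot > 0`, by a full bootstrap over
draws with refitting — the bootstrap is the honest choice when an SE
enters a formal comparison.

## 3. Study designs and the worth of imperfect information

A `study_design()` couples a sampling model with a summary statistic:
`simulate(inputs, n)` must return one fixed-dimension numeric summary
per draw and consume randomness only through R's RNG. The contract is
validated on probe draws (same RNG state twice ⇒ identical output).
`binary_design()` observes Z ~ Binomial(n, p⁽ʳ⁾) with T(Z) = Z; custom
designs can return, e.g., maximum likelihood estimates computed from
simulated raw data.

Published information that arrives as "an estimate m with standard error
σ" is priced through the Beta-posterior equivalence: interpreting (m, σ)
as the mean and SD of a Beta posterior under a vague Beta(0, 0) prior
implies an effective binary-study size n = m(1 − m)/σ² − 1
(`ess_from_se`, rounded half-to-even, floored at zero). The EVSI of a
binary study of that size is then the expected value of obtaining such
an estimate. The conversion is exact for genuine Beta posteriors
(n = a + b), decreasing in σ, and maximized at m = 0.5.

## 4. The worked health impact model

The fixture models a scenario where transport PM2.5 emissions are
scaled by D (default 0.5 — halved):

* scenario concentration g₁(μ, π, D) = μ(πD + 1 − π), with μ the
  background PM2.5 concentration (μg/m³) and π the transport share;
* dose–response relative risk g₂(x, d) = 1 + α(1 − e^(−β(x−τ)^γ)) for
  x ≥ τ, 1 below the counterfactual threshold τ;
* cases averted Y = I₀(1 − g₂(g₁(μ, π, D), d)/g₂(μ, d)), with baseline
  stroke incidence I₀ = 18,530 cases/year treated as known.

Uncertainty distributions: μ ~ log-normal(2.7, 0.3) (≈ 8–27 μg/m³ at
95%), π ~ Beta(5.7, 8.9) (mean 0.4, SD 0.12, 95% limits ≈ 17–64%),
sampled independently (only marginals are available to inform them).
The decision variant adopts the policy if it is expected to avert at
least k = 500 cases/year, i.e. NB₂ = Y − k against NB₁ ≡ 0.

**Dose–response uncertainty.** The joint distribution of
d = (α, β, γ, τ) is derived the way such curve posteriors are built in
practice: perturb the evidence table's log relative risks by their
standard errors, refit the curve by least squares on the log-RR scale
for each perturbation, and keep the sample of fits — capturing the
strong correlation among the four parameters. Fitting is
log-parameterized for positivity, bounded (α ≤ 10, β ≤ 2,
0.1 ≤ γ ≤ 5, τ ≤ min exposure) to keep fits off the flat-curve ridge
α → ∞, β → 0 on which the parameters are unidentified, and multistarted
(3 starts, jittered on the log scale) against local optima. Fits that
fail to converge are dropped and resampled; if fewer than 90% converge
the generator errors with diagnostics rather than returning a biased
sample.

**What the synthetic table emulates — and does not.** The evidence table
behind the fixture (`synthetic_dr_table()`) is the curve g₂ evaluated at
7 exposures 5–35 μg/m³ from reference parameters
d* = (0.6, 0.06, 1.2, 4) with SE 0.05 on log RR, chosen once to give
relative risks in the 1.0–1.6 range typical of published PM2.5–stroke
curves. The real source sample behind the original analysis is not
published, so fixture-level results (credible intervals, EVPI in cases,
per-parameter EVPPI values) are *qualitative analogues*: the tests
assert orderings and structural properties (transport share most
valuable, dose–response group intermediate, background concentration
least; plug-in point estimate biased relative to the Monte Carlo mean),
never the unpublished numbers. Passing tests demonstrate that the
machinery reproduces the *findings' structure* on data of realistic
shape — not that real-data results would be numerically identical.

**Sensitivity analysis.** `tornado_fixed()` varies each parameter
between its 2.5%/97.5% credible limits with the others at their medians;
`tornado_probabilistic()` instead reports E[f(θ) | parameter = limit],
marginalizing over the rest by Monte Carlo — valid only under
independence, which is checked empirically (refusal beyond |r| > 0.1).
The four dose–response parameters are too correlated to vary one at a
time, so they are conditioned jointly on two whole extreme curves: the
draws attaining the 2.5% and 97.5% nearest-rank order statistics of the
strength ratio ρ = g₂(x_L)/g₂(x_U) (defaults x_L = 10, x_U = 15 μg/m³,
the approximate scenario and base-case concentrations). Rows are
ordered by output range, the conventional tornado layout.

## 5. Bias and hierarchical evidence models

**Probabilistic bias.** When evidence on a proportion is indirect, the
context-specific value is π₀ = expit(logit(π_a) + δ),
δ ~ N(shift, σ²); the logit construction preserves (0, 1) support for
any σ. The bias SD is elicited on the ratio scale: `solve_bias_sd()`
finds σ such that the chosen quantile (default 0.9) of π₀/π_a equals the
elicited ratio, by bisection (tolerance 10⁻⁴) on a fixed
common-random-numbers sample of 10⁵ draws — fixing the sample makes the
objective monotone and smooth in σ, so bisection is exact up to
tolerance. The qualitative consequence asserted in the tests: more
probable bias raises the relative value of unbiased (context-specific)
information and lowers that of biased information.

**Hierarchical evidence.** With estimates x_i from M exchangeable areas,
logit(x_i) ~ N(logit(π_i), s_i²) and logit(π_i) ~ N(μ, σ²), with
hyperpriors μ ~ N(0, 10²) (effectively flat on the logit scale) and
σ ~ half-Normal(0, 1) (weakly informative; keeps 6-area fits proper
without forcing heterogeneity) — both configurable. The target area is
a new exchangeable draw: logit(π₀) ~ N(μ, σ²) integrated over the
hyperparameter posterior. Sampling uses JAGS (4 chains, 1000
adaptation, 2000 burn-in, ≥ 4000 kept iterations per chain, per-chain
seeds derived from the user seed); any monitored R-hat above 1.05 is an
error, not a warning. The six-area demonstration table
(`synthetic_areas()`) is synthetic with documented seeds — the original
multi-area values are not published — with logit-scale between-area SD
0.8 ("high") or 0.15 ("low") around a 0.4 centre, and per-area
measurement SD 0.15.

## 6. Numerical conventions and degenerate inputs

* Predictors are standardized internally and given collision-proof
  names (a user column named `pi` must not shadow the base constant in
  a formula).
* Constant predictors are rejected as rank-deficient; constant responses
  short-circuit to an exact constant surface.
* Extrapolation beyond the training range in `predict_surface()` warns.
* `sd_remaining()` = sqrt(var(Y) − EVPPI) estimates the SD that would
  remain after learning φ; note it is derived from the expected
  remaining *variance*, which is not quite the expectation of the
  remaining SD. EVPPI above var(Y) (Monte Carlo noise) is clipped with
  a warning, as is `proportion_explained()` outside [0, 1].
* CSV I/O writes 17 significant digits so round trips are exact; results
  JSON carries a `schema_version`.
* All stochastic entry points take explicit integer seeds, use a local
  RNG stream, and restore the caller's RNG state.

## 7. Problem sizes used in the shipped checks

The test suite verifies closed-form values at the sizes where their
Monte Carlo error is well below the assertion tolerance: R = 10⁵ for the
standard-normal decision EVPI/EVPPI (truth 1/√(2π)), R = 10⁴ for the
Beta-binomial EVSI family (truth V₀·n/(a+b+n)), R = 5000 with a
500 × 500 nested-Monte-Carlo oracle for backend cross-validation, and
R = 5000 for the health impact fixture — the scale at which grouped
nonparametric regression becomes trustworthy. These sizes are the
package's own accuracy choices and are stated here so users can judge
what the checks do and do not establish.

## 8. Known limitations

* Joint EVPPI above 15 parameters is refused; microsimulation-scale
  VoI needs methods beyond regression emulation.
* EVSI is computed by summary-statistic regression only; moment
  matching, importance sampling and Gaussian-approximation algorithms
  are out of scope.
* The GP backend's variance estimates run a few percent low on noisy
  problems (regularization); prefer splines when p ≤ 4, and compare
  backends when results are close to a decision boundary.
* Net benefit is per population as supplied; scaling per-person benefit
  to population totals (and discounting) is the caller's concern.
* The probabilistic tornado requires independence of the varied
  parameter from the rest; correlated structures must be grouped.
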