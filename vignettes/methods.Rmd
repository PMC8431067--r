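---
title: "Measuring income-related inequity in unmet healthcare needs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring income-related inequity in unmet healthcare needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hinequity)
library(dplyr)
```

## The question

When healthcare is rationed — as it was when providers postponed and denied
appointments during the first COVID-19 wave — the equity question is not
whether unmet need differs between poor and rich, but whether it differs
*beyond what differences in need justify*. Older people with worse health
legitimately have more appointments at stake, so some income gradient in
postponed care is expected wherever health and income correlate. `hinequity`
measures the total income gradient of a binary unmet-need outcome, removes
the part attributable to need, and attaches honest uncertainty to what is
left.

## The model

**Fractional income ranks.** Each individual in a group (country) is ranked
by equivalent household income, with equivalent income defined by the
single-parameter (Buhmann) scale `income / hh_size^theta`. The rank of a
unit is the cumulative sampling-weight share of strictly poorer units plus
half its own share, so the weighted mean rank is exactly 1/2. Ties receive
the midpoint rank of their block, making the ranks invariant to input order
— without this, bootstrap replicates (which duplicate rows heavily) would
not be reproducible. `theta` defaults to 0.5, the conventional square-root
scale; it is exposed because reasonable analyses vary it between 0 and 1.

**Concentration indices.** For outcome `y` with weighted mean `m` and rank
`r`, the package computes

* standard CI = `2 cov_w(y, r) / m` — twice the area between the
  concentration curve and the line of equality; positive when the outcome
  concentrates among the better-off;
* Erreygers-corrected CCI = `8 cov_w(y, r) = 4 m CI` — for a binary outcome
  the standard CI is bounded by `[m - 1, 1 - m]`, so populations with
  different prevalences are not comparable; the Erreygers correction
  restores a common `[-1, 1]` scale;
* generalized GCI = `2 cov_w(y, r)` — no division by the mean, defined for
  mean-zero variables such as model residuals.

All three are weighted-covariance forms. Textbook summation formulas for
these indices are sometimes written without demeaning the ranks; taken
literally those expressions are nonzero for a constant outcome. The
covariance forms used here demean by construction, return exactly zero for
constant outcomes, and reproduce the verbal definition and the stated
bounds.

**Decomposition and the horizontal inequity index.** If the outcome were
linear in its regressors, `y = a + sum_j b_j x_j + e`, the corrected index
would decompose exactly (one line of covariance algebra) as

```
CCI(y) = sum_j 4 b_j GCI(x_j) + 4 GCI(e)
       = sum_j 4 b_j xbar_j CI(x_j) + 4 GCI(e).
```

Each regressor contributes its income gradient `CI(x_j)` scaled by how much
it moves the outcome (`b_j xbar_j`, the elasticity numerator). For a binary
outcome a weighted probit is fitted instead, and linearized with *partial
effects at weighted sample means*: `m_j = dnorm(xbar' beta) * beta_j`. The
decomposition is then an approximation; the approximation error is carried
in the residual `u = y - (a_m + sum_j m_j x_j)` and always reported as
`4 GCI(u)`, never absorbed into contributions. The intercept of the
linearization is `a_m = mean_w(y) - sum_j m_j xbar_j`, which gives `u`
weighted mean zero; since a constant has zero GCI, this choice cannot move
any reported term. With `model = "ols"` the identity is exact to numerical
precision, which the tests exploit.

The horizontal inequity index is

```
HI = CCI - sum_{j in need} contribution_j
```

— the income-related inequality not explained by need (age group, gender,
self-assessed health, worsened health, chronic conditions, cancer, ADL and
IADL limitations). Under "equal treatment for equal need", HI = 0. For an
unmet-need outcome, HI < 0 means the poor face more unmet need than their
needs explain (inequity favouring the rich). Contributions are computed as
`4 m_j GCI(x_j)`, the algebraically equivalent form of
`4 m_j xbar_j CI(x_j)` that remains defined when a regressor has mean zero.
An alternative inequity measure by indirect standardization
(`hi_indirect()`: CCI of the observed outcome minus the corrected-scale
index of need-predicted probabilities with non-need regressors at their
means) is provided as a cross-check; the subtraction-of-contributions form
is the default and the one used throughout.

**Which variables count as need** is an analysis choice, not a package
constant: `need_vars()` / `nonneed_vars()` give the defaults (demographics
and morbidity vs. living arrangement, log equivalent income, education, job
situation, urbanicity), and every function accepts other sets. With no need
variables, HI equals CCI exactly.

## Estimation choices

**Probit.** Fitted by a Newton-type iteration on the weighted
log-likelihood using the expected information (Fisher scoring), with
step-halving when a step fails to improve the likelihood and a ridge of
`1e-8 * max(diag(H))` when the information matrix is near-singular.
Convergence requires gradient max-norm `< 1e-8` or relative log-likelihood
change `< 1e-10`, capped at 100 iterations. Perfect separation is detected
from a diverging linear index (|eta| > 30) and reported as a typed error
naming the most extreme coefficient; rank-deficient designs are reported
with the aliased columns. The variance matrix is the sampling-weight
sandwich. Weights are normalized to sum to the sample size, so all results
are invariant to rescaling the weights.

**Robust standard errors for the corrected index.** Via the convenient
regression: `8 var_w(r) y` regressed on `r` by weighted least squares has
slope exactly equal to the CCI, and its heteroskedasticity-robust HC1
sandwich SE (with weights treated as sampling weights) is the reported
standard error. The tests verify the slope identity to 1e-10 and the SE
against an independent sandwich-estimator implementation.

**Bootstrap for HI.** The inequity index is a non-smooth functional of the
whole estimation chain, so its SE comes from resampling individuals with
replacement within the group — 1000 replicates by default — recomputing
ranks, probit and decomposition inside each replicate (rank variability is
part of the estimator and must propagate). Intervals are bias-corrected
percentile (BC): `z0 = qnorm(share of replicates below the estimate)`
(midpoint convention for ties), endpoints at percentiles
`pnorm(2 z0 +/- qnorm(1 - (1-level)/2))`. BC rather than BCa: the
acceleration constant would require a jackknife pass that the underlying
analysis convention does not use. All requested levels are computed from
one replicate set. Replicates that fail — degenerate resampled outcome,
separation — are dropped and counted; more than 5% failures flags the
result unreliable rather than silently averaging. Internally a resample is
aggregated into multiplicity-scaled weights (a row drawn `m` times with
weight `w` equals one row with weight `m w` for every weighted statistic in
the chain, including midpoint tie ranks), which cuts replicate cost by
roughly a third.

**Significance flags** follow the two-sided normal convention: `*` p < 0.1,
`**` p < 0.05, `***` p < 0.01, applied to estimate/SE pairs — analytic for
CCI, bootstrap for HI.

**Batch runs.** `run_analysis()` derives an independent seed per group x
outcome from the master seed and the labels (not from a positional
counter), so adding a country never perturbs another's replicate stream.
Groups that fail produce NA rows with a logged reason; the batch never
aborts. Output CSVs are written at full precision and round-trip through
`summarize_results()`.

## The synthetic generator

Real analyses of this kind run on restricted-access survey microdata, so
the package ships a generator whose truth is known by construction.
Covariates mimic an ageing survey: age bands with the pooled proportions of
a 50+ European sample (47% aged 50-64 down to 7% aged 85+), 55% women,
lognormal household income, household sizes 1-5 (27% living alone),
self-assessed health graded by age and income through an explicit latent
index, chronic counts rising with age and worse health, education graded by
income, job status switching at retirement age, mildly variable calibrated
weights. Outcomes follow a probit:
`y* = alpha + x'beta + z'gamma + delta log(eq_income) + eps`, `y = 1{y* > 0}`,
with standard normal `eps` (so the estimation model is correctly specified;
a logistic toggle exists for misspecification experiments). `delta = 0` and
`gamma = 0` makes true inequity exactly zero, because all systematic income
gradient then flows through need.

Four presets cover the cases the estimator must distinguish:
`null_need_only` (true HI = 0), `pro_rich_denial` (`delta = -0.25` on
denial: the poor are denied more at equal need, HI < 0),
`pro_poor_postponement` (`delta = +0.2`, HI > 0), and `share_like`
(prevalences calibrated to the pooled survey values, postponed 0.2533 and
denied 0.0540, with mild non-need effects). Preset intercepts were
calibrated once by large-n simulation against those prevalence targets and
frozen; the need-slope vector (for example +0.45 for poor self-assessed
health, +0.35 for cancer, +0.08 per chronic condition on the probit scale)
is shared across presets.

What the generator does *not* emulate: multi-stage sampling designs and
calibration raking (weights are i.i.d.), panel attrition, income item
non-response and imputation, country heterogeneity beyond location/scale of
income, and any misreporting. Passing tests on these presets therefore
demonstrate correctness of the estimator under a clean, correctly specified
DGP — not robustness to the messiness of real survey data.

## What the checks compute, at which sizes

The test-suite simulations use sizes chosen to separate signal from
Monte-Carlo noise while staying desk-scale: identity and oracle checks at
n <= 200 (100 random instances for the OLS adding-up identity); null-HI
centering with 200 replicates at n = 20,000; interval coverage under the
null with 200 trials of n = 2,000 and 200 bootstrap replicates each;
sign-recovery with 50 trials of n = 20,000 and 200 bootstrap replicates.
`scripts/acceptance.R` re-runs the same machinery (prevalence emulation at
n = 50,000, inequity recovery at n = 20,000 with a 1000-replicate
bootstrap, null coverage with 100 trials) and additionally scores the
normal-approximation significance flags against the published per-country
reference table shipped in `inst/extdata` — the package reproduces the
published 90% and 95% significance classification for all 50 corrected-index
entries, and flags three entries whose published stars understate the
z-score implied by their own printed estimate/SE pairs.

## A worked example

```{r example}
d <- generate_dataset(preset_scenario("pro_rich_denial", n = 5000, seed = 42))
dec <- decompose_cci(d, "y_denied")
glance(dec)
tidy(dec, roll_up = TRUE) |> arrange(contribution)
bootstrap_hi(d, "y_denied", n_reps = 200, seed = 7)
```

Negative HI with an interval excluding zero recovers the injected pro-rich
inequity in denial.

## Limitations

* HI inherits the standardization assumption: need not captured by the
  regressors that correlates with income is misattributed to inequity. The
  probit linearization leaves an approximation residual that is reported
  but not decomposed further.
* Inference accounts for sampling weights only; clustering and
  stratification of a real survey design are out of scope, as are income
  imputation and inter-group (Oaxaca-style) decompositions.
* The Erreygers correction is the only bounded-outcome normalization
  implemented; the Wagstaff alternative is deliberately not offered.
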