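---
title: "Predicting dry matter intake of lactating dairy cows: model, development procedure and validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dry matter intake of lactating dairy cows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kfsdmi)
```

## The problem and the model

Dry matter intake (DMI, kg/d) of a lactating cow reflects two opposing
forces: the energy demand of maintenance and milk synthesis pulls intake
up, while rumen fill limits it. The KFSD equation captures exactly this
structure with three routinely measurable inputs:

$$\mathrm{DMI} = 4.103 + 0.112\,\mathrm{MBW} + 0.284\,\mathrm{FCM} - 0.119\,\mathrm{NDF}$$

- **MBW** (kg^0.75^), metabolic body weight, is proportional to
  maintenance energy demand; its coefficient is kg DMI per kg^0.75^.
- **FCM** (kg/d), 4% fat-corrected milk, standardizes milk yield to an
  energy-equivalent basis. The package uses the Gaines linear form
  `FCM = 0.4·MY + 15·fat yield`, which is the identity at 4% milk fat.
  (The standard's own FCM formula is not printed with the equation; the
  Gaines form reproduces the development database's FCM column from its
  milk-yield and fat summaries to within aggregation error, which is why
  we adopt it.)
- **NDF** (% of dietary DM), the cell-wall fraction of the diet, proxies
  rumen fill; its negative coefficient is kg DMI per percentage point.

Early-lactation intake depression is modelled multiplicatively with the
Roseler lag function $1 - e^{-r(\mathrm{WOL} + c)}$ of the week of
lactation. `Lag[2]` (peak milk in month 2) uses $r = 0.316$, $c = 2.36$;
`Lag[3]` uses $r = 0.192$, $c = 3.67$. Two numerical choices deserve
notice:

- The `Lag[2]` rate appears in the source standards both as 0.316 and as
  0.318. We default to 0.316 — the value printed with the comparison
  tables — and expose `rate` in `lag_spec()` so either variant can be
  requested.
- The lag is applied at **all** weeks of lactation, not switched off after
  week 16: the multiplier is within 10^-6^ of 1 by week 60, so the smooth
  form is numerically indistinguishable from a truncated one while
  avoiding a discontinuity.
- Whether the published evaluation applied `Lag[2]` to the KFSD equation
  is not stated; the bare `"kfsd"` model id therefore predicts without
  lag and `"kfsd_lag2"` applies it.

Comparator equations (NRC 2001, CNCPS, the Japanese feeding standard) are
implemented exactly as printed, including the JFS parity-specific built-in
lactation adjustment. Linear intake equations can go negative at extreme
inputs outside any supported range; predictions are clamped at 0 with a
warning rather than returned negative.

All percentages in the package are percentage points (NDF 33.4 means
33.4% of DM, never 0.334), enforced by range checks.

## Data pipeline

Literature treatment means enter through a fixed CSV schema. The
inclusion filters retain records with reported milk yield, Holstein
breed, DMI ≥ 2% of body weight, forage 30–<100% of dietary DM, NDF ≥ 25%
DM and a reported week of lactation. Two readings were genuinely open:

- "forage … less than 30% or 100%" is read as excluding FpDM < 30 *and*
  all-forage (FpDM = 100) diets, with the 30% boundary retained;
- a record whose value for a rule's quantity is missing fails that rule
  (it cannot be verified), while records with unusable DMI or body weight
  are counted in a separate `parse` bucket.

Rejections are attributed to the *first* failing rule in the printed
order, making filter reports deterministic; the counts always reconcile
with the input size, and filtering is idempotent.

Studies contributing at least four retained means go to the development
set, the rest to evaluation. The original procedure additionally kept
exactly four means per development study; because the within-study
selection rule is unstated we retain all observations by default and
provide `cap_per_study(cap = 4, seed)` for users who want the balanced
variant (random without replacement, seeded).

## Two-phase model development

Phase one fits, for every admissible predictor subset, the random
coefficient model $y = X\beta + Zu + e$ with study as the random variable:
each study gets an independent random intercept and one independent
random slope per predictor (a diagonal G block per study; no covariances),
with $e \sim N(0, \sigma^2 I)$. Fitting is REML via `lme4::lmer()`, the
standard engine for exactly this model class. Subsets are compared by
information criteria computed from the REML log-likelihood with $q$ = the
number of variance parameters (the $p$ random-effect variances plus
$\sigma^2$): $\mathrm{AIC} = -2\ell + 2q$ and
$\mathrm{BIC} = -2\ell + q\ln s$ with $s$ the number of studies. These
definitions are a package choice — the criteria's exact form is not
printed in the source material — and `bic_n = "obs"` switches BIC to the
N-based variant. Two guards keep the comparison honest:

- all subsets are fitted on a single common complete-case row set, so
  criteria are comparable;
- near-duplicate predictors are never co-selected (exclusion pairs
  `{bw, mbw}` and `{my, fcm}` by default), since the development
  procedure compared these alternatives rather than co-fitting them.
  Subset size is capped at 4 by default because full enumeration is
  exponential.

With a single study the between-study variances are unidentifiable; the
fit collapses to OLS with the variance components reported at the zero
boundary rather than erroring.

Phase two drops the random effects and re-estimates the selected subset
by OLS with classical standard errors — reproducing the original
procedure, which reported fixed-effect SEs from a general linear model
that ignores study clustering. Cluster-robust SEs would be wider; we
reproduce the published choice and note this as a limitation.

## Evaluation statistics

Precision is the $R^2$ of observed on predicted; accuracy is RMSPE. Bias
is assessed by regressing residuals (observed − predicted) on predictions
centered at their mean: the intercept is the mean bias (identical to the
arithmetic mean residual, by the centering identity) and the slope is the
slope bias, each with a two-sided t-test p-value. Useful identities,
verified in the test suite: the observed-on-predicted slope equals
1 + slope bias on the same data, and
$\mathrm{RMSPE}^2 = \text{mean bias}^2 + (1-b)^2\mathrm{Var}(p) +
(1-r^2)\mathrm{Var}(y)$ with population variances.

`compare_models()` drops records lacking any predictor required by *any*
requested model before evaluating, so every model row shares the same n —
the convention used when several equations are compared on one evaluation
database. Seasonal evaluation (`season = "cold"` for Nov–Jan,
`"warm"` for Mar–Jun) filters on the records' month tags.

## Sensitivity analysis

`run_sensitivity()` emulates a spreadsheet-risk-style analysis:

1. **Input distributions.** `fit_input_distribution()` fits seven
   candidate families (normal, lognormal, gamma, Weibull, logistic,
   uniform, triangular) by maximum likelihood and computes three
   goodness-of-fit statistics: a χ² test on equal-probability bins
   (⌈2·n^0.4^⌉ bins), Kolmogorov–Smirnov and Anderson–Darling. The
   variable is treated as normal when all three tests fail to reject
   normality at α = 0.05; otherwise the family with the best mean rank
   across the three statistics wins. Because the parameters are estimated
   from the data, fixed-table KS/AD critical values would be
   anti-conservative; the normality-gate p-values are therefore
   calibrated by a parametric bootstrap (500 resamples by default).
2. **Sampling.** Latin hypercube: one draw per equal-probability stratum
   per variable, strata paired independently across variables by default.
   The published analysis does not state any input correlation structure,
   so independence is the default; a rank-correlation matrix can be
   supplied and is induced by Iman–Conover reordering.
3. **Convergence.** Batches (default 1,000 samples) are appended until
   the running mean and SD of the model output each change by less than
   1% between consecutive batches (minimum 3 batches) — the "<1%
   convergence" criterion monitored on summary statistics, as
   spreadsheet-risk tools do — with a 10^6^-sample cap.
4. **Ranking.** Standardized regression coefficients: OLS of the output
   on z-scored inputs, divided by the output SD. For a deterministic
   linear model with independent inputs the coefficient for input $j$ is
   $\beta_j \mathrm{SD}_j / \mathrm{SD}_{out}$ and the squared
   coefficients sum to 1; both properties are exercised in the tests.

At the pooled database moments (BW ~ N(642, 50²) converted to MBW,
FCM ~ N(31.5, 6.8²), NDF ~ N(33.4, 4.5²), independent), the analysis
ranks FCM first with a standardized coefficient that rounds to 0.9 and a
negative NDF coefficient. Note that under independence the closed-form
NDF value is ≈ −0.25; a published value of −0.2 for NDF would require an
input correlation structure we have no record of, so only the FCM value
and the ordering are treated as reproducible. A standardized coefficient
is *not* "kg DMI per 1% NDF": raw and standardized scales coincide only
when the input SD equals the output SD.

## Synthetic data: what it emulates and what it does not

`generate_literature()` emulates a study-clustered literature database:
inputs drawn from truncated normals at the development-database moments
(BW 640.33 ± 50.29 kg, MY 34.43 ± 5.81 kg/d, fat 3.49 ± 0.46%, NDF
33.35 ± 4.51% DM, FpDM 53.35 ± 12.82%, truncated so rules iii–v hold by
construction), FCM derived from MY and fat so milk variables are mutually
consistent, and DMI generated as the KFSD equation plus a study random
intercept (SD 1.5 kg/d) and residual noise (SD 1.0 kg/d). Those two SDs
are a choice: together they give a generated DMI SD ≈ 2.6 kg/d against a
marginal equation-driven spread of ≈ 2 kg/d, landing the total near the
development database's DMI SD (3.18 kg/d) with roughly two-thirds of the
unexplained variance between studies, as is typical of meta-analytic
feed-intake data. Week of lactation, which the database summaries do not
report, is drawn as a truncated normal (mean 15, SD 8, floor 1, cap 45
weeks, rounded) — a mid-lactation-heavy spread typical of published
trials. Residuals that would push a record below the 2% DMI/BW inclusion
floor are redrawn, a negligible perturbation five residual-SDs from the
mean.

The main realism gaps, deliberate and documented: inputs are sampled
independently (the database summaries give moments, not covariances — an
optional correlation matrix exists), there are no random slopes in the
default generative truth, and no publication-selection effects. Passing
recovery tests on this generator therefore shows the estimation machinery
is correct, not that the published equation is right for any particular
herd.

`generate_farm()` emulates a November–June automatic-milking feeding
trial (February removed, 32 cows, 11 primiparous) at the trial's monthly
moments (BW 751 ± 79.5 kg, MY 31.2 ± 7.13 kg/d, fat 4.2 ± 0.63%, ration
NDF 40.0 ± 0.98% DM). Observed DMI is the KFSD prediction plus residual
noise (SD 2.4 kg/d, chosen to land RMSPE in the mid-2-kg range typical of
per-cow monthly means) plus an additive cold-season offset (Nov–Jan,
default 0) that emulates intake above the thermoneutral prediction in
cold weather. Because observed intake is generated *from* the equation,
the warm-season evaluation is unbiased by construction and the
cold-season mean bias equals the injected offset — an end-to-end oracle
for the seasonal evaluation path, not a statement about real cold-season
physiology. TMR/concentrate intake components are generated (≈ 79/21
split) but used by no equation; records beyond 3 SD of a cow's own mean
are flagged as outliers rather than silently removed.

Both generators are deterministic given their seed; identical configs
yield identical tables.

## Numerical choices and degenerate inputs

- Truncated-normal sampling is by rejection with a 10⁴-attempt cap and an
  explicit infeasibility error when the truncation region holds < 10⁻⁶
  probability mass.
- Constant predictions make the evaluation regressions degenerate and
  raise a classed error rather than returning NaNs; batches of
  predictions flag individual bad records (`NA` + status) instead of
  aborting.
- Variance components sit naturally at the 0 boundary (lme4's constrained
  optimizer); singular fits are reported, not errored.
- All stochastic routines take explicit seeds; derived stream seeds stay
  below 2³¹.

## Problem sizes in the test suite

The suite exercises full development-database scale where it matters
(458 records × 20 seeds for coefficient recovery; 10,000-sample LHS for
the sensitivity ranking) and reduced scale where the property being
checked is size-invariant (40-study databases for selection consistency;
200 replicates for variance-component recovery). The complete suite runs
in well under a minute of compute on a single core.

## Known limitations

- Phase-two SEs ignore study clustering (faithful to the original
  procedure); treat them as optimistic.
- REML information criteria compare models with different fixed effects,
  which is statistically debatable but mirrors the original SAS MIXED
  workflow; the penalty counts only variance parameters.
- The environmental/temperature intake adjustment that would correct the
  cold-season bias is out of scope, as are breeds other than Holstein and
  per-meal intake dynamics.
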