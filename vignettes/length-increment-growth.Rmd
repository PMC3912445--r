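---
title: "A time-free length-increment growth law for fish cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A time-free length-increment growth law for fish cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lengthlaw)
```

## The model

`lengthlaw` implements a growth law for fish in which the length increment
over one observation step is proportional to the distance left to a fixed
maximal length:

$$ dL = k \cdot (L_{\max} - L_s), $$

where $L_s$ is the current (start-of-interval) length, $L_{\max}$ a fixed
maximal length, and $k$ a dimensionless coefficient that absorbs the
environment — food availability, temperature — over that step. The model
carries no internal clock: "one step" is simply the interval between two
consecutive observations (a year for survey data, a sampling interval for
laboratory fish). This is what lets increments be summed arithmetically
across all year-classes present in the same year, which a time-indexed
growth curve cannot do.

Two consequences shape everything in the package:

* Rearranged, $dL = -k L_s + k L_{\max}$ is a straight line in the
  increment-versus-length plane, so $(k, L_{\max})$ are estimable by
  ordinary least squares: $k$ is the negative slope and $L_{\max}$ is
  the x-intercept ($-\mathrm{intercept}/\mathrm{slope}$; equivalently
  the y-intercept equals $k L_{\max}$).
* Under constant $k$ the recursion solves in closed form,
  $L_n = L_{\max} - (L_{\max} - L_0)(1-k)^n$: the remaining gap decays
  geometrically. $L_{\max}$ is reached (in the limit), not approached as
  a von Bertalanffy-style asymptote parameter; it is a fixed value with
  a direct physical reading.

Model assumptions: the animal cannot shrink and cannot overshoot
$L_{\max}$ in one step, hence $0 \le k \le 1$; `growth_params()` rejects
anything else. Floating-point comparisons against $L_{\max}$ use an
absolute tolerance of $10^{-9}$ length units.

## From survey tables to increment pairs

Survey data arrive as a year × age matrix of mean lengths
(`age_length_table()`). A year-class (cohort) born in year $b$ lies on
the diagonal: age $a$ in year $b + a$. `extract_cohorts()` reads each
diagonal; cohorts seen at fewer than two ages are dropped, and missing
cells simply leave gaps. `cohort_increments()` forms
$dL_a = L_{a+1} - L_a$ for consecutive ages only, pairing each increment
with the *start-of-interval* length $L_a$ — the law is written with
$L_s$, the length before the increment, and increment-by-length plots
are read the same way. For sub-annual data with uneven sampling, pass
observation times and the increment is normalised per elapsed unit.

Two pooling views exist (`pool_increments()`): `"per_age_average"`
averages $L_a$ and $dL_a$ across year-classes at each age, unweighted
(no weighting scheme is imposed on survey means of unequal provenance);
`"pooled"` keeps all raw pairs. Negative observed increments are
retained for fitting — they are legitimate measurement noise around the
line, and discarding them would bias the slope — but flagged.

## Estimation and the model comparison

`fit_linear()` is ordinary least squares of $dL$ on $L$. The growth
parameters are derived only when the slope is negative; a flat or rising
increment profile cannot satisfy the law and leaves `k`/`l_max` as `NA`
rather than producing a nonsensical negative $k$. `fit_quadratic()` fits
the second-order alternative $dL = c_2 L^2 + c_1 L + c_0$ and records
the parabola's orientation (some pelagic stocks show a *convex*,
inverted parabola).

The two models are nested, so `compare_models()` uses the
extra-sum-of-squares F-test:

$$ F = \frac{(SS_{lin} - SS_{quad})/1}{SS_{quad}/(n-3)}, $$

with an upper-tail p-value from $F(1, n-3)$ — the standard one-sided
form for a variance-ratio test of nested fits. The quadratic is
preferred iff $p < \alpha$ (default 0.05). Exact ties, where both models
fit perfectly (residual sums of squares below $10^{-12}$ relative to the
response scale), go to the simpler linear law. A small-sample AICc
comparison is computed alongside and can be made the deciding criterion
with `criterion = "aicc"`, but the F-test is the default because it
matches the p-value style of standard nested-regression reporting.

Confidence intervals (`growth_ci()`): $k = -\text{slope}$ inherits the
slope's standard error; $L_{\max} = -b_0/b_1$ gets a delta-method
standard error from the coefficient covariance. Both use $t_{n-2}$
quantiles.

## Deviating young ages and per-age k

In several wild stocks the youngest one or two ages fall below the line
fitted to older fish — read as a lowered environmental $k$ early in
life, not as a failure of the law. `detect_deviating_ages()` therefore
drops the *youngest remaining* age while the fit on the rest has
$R^2$ below a threshold (default 0.98, the quality of fit typical for
the well-behaved older ages) and at least `min_points` (default 3) pairs
remain. Only a prefix of young ages can ever be excluded — every
deviation this analysis targets concerns young fish — and the first
(largest) suffix meeting the threshold wins. If none does, the full set
is returned flagged, never silently truncated. The procedure is
idempotent on its own output.

Ages inside the core fit inherit its $k$ (`source = "on-line"`).
Excluded young ages get an individual coefficient
$k_a = dL_a / (L_{\max} - L_a)$ (`k_for_age()`), the slope of the
straight line from their point to $(L_{\max}, 0)$, against a *shared*
$L_{\max}$: the unweighted mean of the per-cohort core estimates
(`k_by_yearclass()`). A negative single-age increment clamps to
$k_a = 0$ with a flag — unlike a regression, a one-point ratio has no
noise-cancelling context, and $k$ cannot be negative. Cohorts whose core
fit leaves $L_{\max}$ undefined propagate as flagged rows.

## Projection and biomass

`project_cohort()` applies the law stepwise under a per-step $k$ series
(environmental variability enters here); with a constant series it
reproduces the closed form exactly. Weight conversion uses Fulton's
condition factor, $W = cL^3$ (`length_to_weight()`; the shipped default
0.0104 maps cm to g, the classic cod value), and `stock_biomass()` sums
`abundance * c * L^3` over the cohorts present in a step.

`project_stock()` accepts exogenous per-step survival multipliers —
mortality and recruitment are inputs, not modelled, since stock
assessment integration is outside this package's scope. A series of the
wrong length is an error, never recycled: silent recycling hides
configuration bugs. End-of-step states are mathematically identical
whether growth or mortality acts first within a step, so the `order`
flag instead controls the one quantity that does depend on it: the
length at which removed fish are weighed in the `removed_biomass`
column (`"growth_first"` = post-growth length, `"mortality_first"` =
pre-growth). The package exposes both without endorsing either.

## The synthetic generator

`generate_table()` inverts the analysis: it grows cohorts by the law
itself with known $(k, L_{\max})$, lays them on the year × age grid, and
adds observation noise. Its defaults are the conditions of a
herring-scale study — ages 1–9, $L_{\max} = 354$ mm, $k = 0.3$ per year,
11 year-classes, 100 mm mean length at age 1 — so synthetic output is
directly comparable to typical pelagic survey tables. Two distinct
noise channels exist and can be combined:

* **Observation noise** (`noise_sd`) is additive Gaussian on the
  *observed mean lengths*, truncated at zero — survey means are the
  measured quantity, so that is where measurement error belongs.
* **Process variability** in $k$: per-age overrides (e.g. halving $k$
  at ages 1–2 to emulate depressed young-fish growth) and
  `generate_k_series()` for projection scenarios (iid lognormal shocks,
  median-unbiased, clamped into $[0,1]$).

The RNG is fixed (Mersenne-Twister) and the seed fully determines the
output; generation saves and restores the caller's RNG state. What the
generator does *not* emulate: within-age length distributions,
age-reading error, survey selectivity, and spatially varying
catchability. Tests passing on synthetic data therefore demonstrate
correctness of the estimation machinery under the model's own
assumptions plus idealised Gaussian survey noise — not robustness to
every failure mode of real survey data.

## Validation design and problem sizes

The validation suite checks, among others: exact equivalence of the
closed form and the iterated recursion (1,000 random parameter draws,
relative tolerance $10^{-9}$); exact generate-then-fit closure without
noise (100 random specifications); agreement of both fits with
independently coded normal-equations oracles (100 instances,
$10^{-8}$); F-test rejection calibration at $\alpha = 0.05$ under a true
linear law (10,000 replicates, 9 pairs); parameter recovery and interval
coverage under 5% survey noise (500 replicates); deviating-age detection
with halved young-age $k$ (100 specifications, noiseless and at 2%
noise); exact weight–length inversion and biomass additivity; and scale
equivariance of all unit-free quantities (50 instances). These sizes
keep the full suite under a minute on one core while leaving Monte Carlo
standard errors well below the asserted margins.

One calibration caveat the suite itself exposes: with noise on observed
mean *lengths*, consecutive increments share noise terms
($dL_a = L_{a+1} - L_a$), so increment errors are negatively correlated
and the regressor is itself noisy. Ordinary least squares then
overstates the estimator's standard error, and the nominal 95% intervals
over-cover (roughly 99% in the suite's own measurement), while the same
interval code covers at the nominal rate when noise enters the
increments independently. The intervals are conservative — safe but
wide — under survey-mean noise; an errors-in-variables correction is a
deliberate non-goal at this stage.

## Worked example

```{r}
spec <- synthetic_spec(growth_params(0.3, 354, "mm"), n_cohorts = 11,
                       ages = 1:9, noise_sd = 2, seed = 1)
tab <- generate_table(spec)
cohorts <- extract_cohorts(tab)
pairs <- pool_increments(cohorts, mode = "per_age_average")
lin <- fit_linear(pairs)
lin
compare_models(lin, fit_quadratic(pairs))
growth_ci(lin)
```

```{r}
proj <- project_stock(
  cohort_state(0L, 10, 1e6, growth_params(0, 35.4, unit = "cm")),
  k_series = generate_k_series(0.3, "lognormal", sigma = 0.15, steps = 8, seed = 2),
  survival = rep(0.8, 8),
  cf = condition_factor(0.0104, length_unit = "cm"))
proj
```

## Known limitations

* $L$ appears on both axes of the fit ($dL$ contains $L_{a+1}$); no
  errors-in-variables correction is applied, and intervals are
  conservative under survey-mean noise (above).
* Per-age averaging across year-classes is unweighted; survey sample
  sizes are not used.
* The deviation detector only ever excludes the youngest ages; a stock
  with mid-life anomalies needs a different tool.
* Units are tags, not a unit system: the package refuses mixed units
  but performs no conversion.
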