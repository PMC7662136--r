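---
title: "The school-closure years-of-life-lost model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The school-closure years-of-life-lost model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolyll)
```

## The question the model answers

When US public primary schools closed in early 2020, the visible cost of
keeping them open would have been additional COVID-19 deaths.  The less
visible cost of closing them falls on the children: missed instruction
depresses final educational attainment, and attainment is one of the
strongest known predictors of adult mortality.  schoolyll implements a
decision-analytic comparison of the two options in a common currency,
years of life lost (YLL):

* **Schools closed** (what happened): direct YLL from recorded COVID-19
  deaths, corrected for death undercounting, *plus* education-mediated YLL
  accrued by the roughly 24.2 million public-school children aged 5--11.
* **Schools open** (counterfactual): direct YLL scaled by a
  school-opening mortality ratio.

The decision quantity is the probability, over paired Monte Carlo draws,
that the closed-schools total exceeds the open-schools total.

## Model structure

### Direct YLL

Recorded deaths are taken from a bundled table of deaths by sex and
10-year age band (band labels are treated as band midpoints; 85 is the
assumed maximum age of death).  Direct YLL is `sum(deaths * e(midpoint))`
using the band life expectancies carried by the table.  Undercounting is
corrected by a multiplicative ratio drawn from PERT(1, 1.22, 2.44): the
minimum encodes that excess deaths cannot be negative, the mode comes from
early-2020 New York excess-mortality comparisons, and the maximum doubles
the mode.

### Education-mediated YLL

The pathway has two stages, each with its own uncertain parameter:

1. **Closure to attainment.**  Ten missed school days reduce final
   attainment by 0.0262 (SE 0.0064) years for boys and 0.0217 (SE 0.0062)
   years for girls -- quasi-experimental estimates from prolonged Argentine
   teacher strikes.  Coefficients are drawn from a normal truncated at 0
   (closures cannot raise attainment).
2. **Attainment to mortality.**  Each year of attainment multiplies annual
   mortality by a relative risk RR, drawn normal with mean 0.75 and SD
   derived from the 95% CI (0.60--0.90) as `(0.90 - 0.60) / (2 * 1.96)`,
   the only SD consistent with a symmetric normal reading of the interval
   and no stated standard error.  Losing `L` years multiplies annual death
   probabilities by `RR^-L` from the child's current age onward.

A child's loss is the difference in (discounted) remaining life expectancy
between the baseline life table and the hazard-adjusted one.  Population
YLL sums `count * per-child loss` over all state x sex x race x age cells,
with one RR draw and one per-sex coefficient draw shared across cells
within an iteration: the model propagates *parameter* uncertainty, which
is systematic across children, not per-child sampling noise.

### The counterfactual and the comparison

The open-schools scenario multiplies the undercount-corrected direct-YLL
draws by an independent mortality-ratio draw from PERT(1, 1.93, 2.85):
minimum 1 (young children may not measurably influence spread), maximum
2.85 (the largest published closure-effect estimate), mode the average of
the two published ratios.  Direct-YLL draws are shared between scenarios
(a paired comparison; `paired = FALSE` gives independent undercount draws
instead), and the exceedance probability is the fraction of draws where
closed-schools total YLL is strictly larger.

## Life-table machinery

Tables are single-year, ages 0 to `omega` = 100, with the terminal
`q(omega) = 1` closing the grid.  Expectancy uses the curtate convention
plus half a year for within-year survival: `e(x) = sum_t S(x+t)/S(x) +
0.5`.  Discounting multiplies each future survival term by `(1+r)^-t`,
with the immediate half year undiscounted and the clock starting at the
child's current age (a "discount from adulthood" variant was considered
and rejected as the default because discounting conventions in
cost-effectiveness practice run from the decision date).

Because no machine-readable life table ships with the analysis, full
tables are reconstructed from the 11 printed `(age, e(age))` anchors per
sex.  The default reconstruction assumes a constant annual death
probability within each inter-anchor segment and solves each segment
backwards so that *every* anchor is reproduced exactly; above age 85 the
hazard grows geometrically at 9% per year (a typical old-age Gompertz
slope) with its level calibrated to the terminal anchor.  A smooth
three-parameter Gompertz--Makeham fit is also provided
(`method = "gompertz-makeham"`); it cannot represent infant mortality and
misses the printed anchors by up to ~0.4 years, so it is not the default,
but it supports simulate-then-fit parameter recovery (tested to within
1%).

Hazard adjustment is proportional on `q` rather than on the continuous
hazard; for the `q <= 0.1`, multiplier `<= 1.5` regime this model operates
in, the two differ by under 1%.

### The accounting horizon

The direct-YLL arithmetic assumes 85 is the maximum age of death.  For
commensurability, the education pathway by default also counts lost
life-years only up to age 85 (`horizon = 85` in `per_child_yll()` and
`population_education_yll()`); the survival model itself still runs to age
100 so the terminal anchor (e(85) of 5.9/7.0 years) is honoured.  This
choice matters: uncapped, the per-child losses rise by roughly 40%,
because much of the survival deficit from a lifelong hazard increase sits
beyond 85.  The horizon is an explicit argument, not a constant.

## Monte Carlo conventions

* One master integer seed spawns labelled substreams (undercount,
  mortality ratio, RR, per-sex coefficients, closure-day assignment), so
  adding draws of one parameter never perturbs another, and any stage can
  be reproduced in isolation.  Draws are bit-identical for a fixed seed,
  and seeded calls restore the ambient RNG state.
* PERT sampling is a scaled beta; truncated normals use exact inverse-CDF
  sampling.  RR draws are plain normal with non-positive values redrawn
  (probability < 1e-21); draws above 1 are retained and yield small
  negative education losses, so the education-YLL distribution touches
  zero from below in well under 1% of draws.
* Summaries are medians with equal-tailed credible intervals; the interval
  mass is a parameter (0.95 default).
* Default problem sizes: 100,000 draws for the scalar stages (attainment,
  undercount, counterfactual) and 10,000 draws for the population stage,
  where each draw prices 2,856 population cells through the survival
  recursion; the recursion is vectorised over draws and states and is
  exactly the cell-by-cell computation, verified against it in the tests.

## The synthetic inputs

No microdata ship with the analysis, so the generator emulates the printed
margins:

* **Population**: 24.2M children (11.4M White, 4.3M Hispanic, 3.6M Black,
  4.9M Other), male fraction 0.512, ages 5--11 uniform, spread over 51
  jurisdictions by a bundled approximate resident-population share vector
  (any share vector can be substituted).  Rounding is largest-remainder
  within race, so every published race total -- and the grand total -- is
  matched exactly, deterministically.
* **Closure days**: a four-parameter scaled beta is calibrated so its
  quartiles equal the published median 54.0 and IQR (48, 62.5); states
  receive its quantiles at evenly spaced probability points (a stratified
  systematic sample), randomly assigned to states by seed.
  Stratification makes the sample median and IQR match the published
  targets for *every* seed; which state gets which duration is the only
  random element, because the published analysis does not report
  state-level durations.
* **Baseline attainment** (mean 13.7, SD 2.1 years) is carried as
  metadata: the YLL model is a pure decrement model and never consumes it.
* Race-specific life-table offsets default to zero (only sex-specific
  expectancies are published); `tables` accepts `"sex:race"` keys for
  stratified tables.

What the generator does *not* emulate: real geographic correlation between
state size and closure length, within-state heterogeneity, non-public
schoolchildren, and any post-May-2020 mortality.  Tests passing on this
synthetic population therefore validate the model arithmetic and the
published national margins, not state-level realism.

## Known limitations and discrepancies

* The published boys' attainment-loss interval (0.08--0.35) is more
  right-skewed than a truncated normal with the stated SE can produce
  (which gives roughly 0.07--0.21); the extra variance source is not
  stated.  This package reproduces the stated parameters and flags the
  interval-width disagreement rather than guessing at an unreported
  mechanism.  Relatedly, the published per-boy mean life loss (0.31 years)
  sits ~15% below what the stated coefficients imply under this package's
  life-table mechanics (~0.36), while the per-girl value matches (0.21);
  no symmetric convention reproduces both sexes at once, and the
  undiscounted population median consequently runs ~20--30% above the
  published 5.53 million.
* Under 3% discounting this package's education YLL is ~20% below the
  published 1.52 million: the loss stream implied by a lifelong
  proportional hazard increase is concentrated at ages 70--85 and is hit
  harder by compound discounting than the published figures suggest.  The
  corresponding exceedance probability lands within a few points of the
  published 53.1%.
* The printed per-band YLL cells were evidently computed from unrounded
  expectancies; recomputation from the printed (0.1-year-rounded) values
  agrees within printed precision for every band except the male age-0
  cell, which is inconsistent with its own row under any rounding.
* The source text quotes deaths through May 30, 2020 while its table is
  titled through June 3, 2020; the bundled fixture follows the table,
  whose deaths sum to the quoted 88,241.
* The published analysis does not state its draw count or seed policy, so
  its exact Monte Carlo noise cannot be replicated, only its distributions.
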