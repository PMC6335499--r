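---
title: "Cohort life expectancy by Chiang's abridged life table: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort life expectancy by Chiang's abridged life table: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortlife)
```

## The estimand and the data

`cohortlife` estimates the remaining life expectancy of a patient cohort at
exact ages, from one follow-up record per person: diagnosis date, age at
diagnosis, exit date, and vital status (`died`, `censored` for loss to
follow-up, `alive_at_study_end` for administrative censoring). The method
is the classical abridged (bridge) life table of Chiang, built on 5-year
age bands from 20 to 64 plus an open 65+ band by default.

Two modelling commitments follow from the registry setting:

* **Left truncation at entry.** A person contributes exposure only from
  their age at diagnosis onward. Rates below the entry age of everyone in
  the cohort are simply not estimable from these data.
* **Non-informative censoring.** Loss to follow-up and the administrative
  study end are assumed unrelated to prognosis. The life table mixes
  people diagnosed across the whole calendar window, so the result is a
  cohort-average ("period-like") summary, not a forecast for any
  individual.

## From records to rates

Each record's follow-up `[entry age, exit age)` is split exactly across
the bands it traverses (Lexis splitting). Ages are exact real years, with
calendar time converted at 365.2425 days per year; no integer-age rounding
is applied, which avoids artifacts at band edges. Bands are half-open
`[x, x+n)`: a death at exactly age 25.0 belongs to 25–29. Person-year
conservation is exact by construction — the per-band pieces sum to the
follow-up duration — and is also verified against an independent day-grid
accumulator (`brute_force_person_years()`) that walks follow-up one day at
a time; the two agree to better than 1/365 person-year per record.

A censored record whose exit date equals its diagnosis date is retained
with zero person-years (and a warning); only for deaths does the
coincidence of diagnosis and exit invalidate the record, which the
eligibility filter removes beforehand.

## The life table

With `D_j` deaths and `PY_j` person-years in band `j` of width `n_j`:

* `m_j = D_j / PY_j`, the occurrence/exposure rate, which under a
  piecewise-constant hazard is the maximum-likelihood estimate of the
  hazard in the band.
* `q_j = n_j m_j / (1 + n_j (1 − a_j) m_j)`, Chiang's rate-to-probability
  conversion, clamped at 1. `a_j` is the average fraction of the interval
  lived by those dying in it; 0.5 is the conventional default and is
  configurable per band. A band with no deaths gets `q_j = 0` exactly.
* the synthetic cohort `l, d, L, T, e` is propagated from an arbitrary
  radix (100,000 by default); every reported rate, probability, life
  expectancy and standard error is invariant to the radix, which the test
  suite asserts.

Two useful exact identities follow from the construction and are enforced
as regression properties: `e_j = (L_j + l_{j+1} e_{j+1}) / l_j` for every
closed band, and `e_w = 1/m_w` at the terminal band. For a *constant* rate
`m` across all bands and `a = 0.5`, the abridged table inverts the
conversion exactly and returns `e = 1/m`; for genuinely piecewise-constant
hazards the `a = 0.5` approximation leaves a small discretisation bias
(about 0.4% for a hazard step from 0.1/yr to 0.05/yr at the first band
edge, well inside sampling noise at realistic cohort sizes).

### The open terminal band

The default terminal convention is exponential: `q_w = 1`,
`L_w = l_w / m_w`, `e_w = 1/m_w`. This requires at least one observed
terminal death whenever anyone survives into the open band; otherwise the
builder stops with advice to extend the open band or to supply
`terminal_e_fixed`, which pins the terminal expectancy at a stated value
(published tables sometimes hold it fixed across strata) and removes the
terminal band from the variance.

### Variance and confidence intervals

The variance of `p_j` is binomial-flavoured, `S²(p_j) = q_j² p_j / D_j`,
defined as zero when `D_j = 0` (the continuous limit). Chiang's variance
of life expectancy sums over closed bands:

\[
S^2(e_i) = \frac{1}{l_i^2} \sum_{j=i}^{w-1}
  l_j^2\,[(1-a_j)\,n_j + e_{j+1}]^2\, S^2(p_j).
\]

That sum stops before the open band, so we add a delta-method term for the
terminal expectancy: treating `D_w` as Poisson, `Var(e_w) = Var(1/m_w)
≈ 1/(m_w² D_w)`, propagated as `(l_w/l_i)² Var(e_w)`. Without this
extension the standard error is visibly understated at ages near the open
band. With it, the reported SE matches the Monte-Carlo standard deviation
of the estimator within a few percent (the acceptance suite checks
agreement within 15% over 500 replicate cohorts), and the nominal 95%
intervals achieve 92.5–97.5% empirical coverage at n = 5,000.

The 95% limits are `e ± 1.96·SE` with the multiplier fixed at exactly
1.96 — the convention of the applied literature this package serves —
rather than `qnorm(0.975)`; other confidence levels use the exact normal
quantile. No small-sample adjustment is applied.

## Eligibility, imputation, and ordering

The eligibility filter retains records with a known diagnosis date
strictly before death (for decedents), a well-formed interval, and age at
diagnosis of at least 20 (configurable). Exclusion reasons are reported
deterministically under a fixed precedence (`missing_diagnosis_date` >
`diagnosis_not_before_death` > `under_age_minimum` > `malformed_record`),
so a record failing several checks is counted once and always under the
same reason.

Missing sex and age are filled by a *single seeded hot-deck*: sex is drawn
from the observed sex distribution within the same transmission-route
category (overall if no such covariate exists), then age from the observed
ages within the record's sex. This preserves the marginals and is
byte-reproducible given the seed. It deliberately does **not** propagate
imputation uncertainty: with both variables missing in well under 10% of
records — the imputer refuses to run above that fraction — the extra
between-imputation variance is negligible next to the sampling variance of
the life table, and a single imputation keeps the whole pipeline
deterministic. Imputation runs *before* filtering, so age eligibility is
judged on imputed ages; the alternative (filtering first) would silently
drop records whose only defect is a missing age.

## Stratified analyses, trends, and the rest

Stratified life tables partition the cohort by a fixed patient attribute
(missing values form an explicit `"unknown"` stratum); exposure is
additive across any partition, which the tests assert. Group membership is
time-fixed at diagnosis — treatment is "ever received" — so the usual
immortal-time caveat applies to treatment contrasts; the package reports,
it does not adjudicate causality. Comparisons use a two-sample z-test on
the two independent Chiang estimates at a reference band:
`z = (e_1 − e_2)/\sqrt{SE_1² + SE_2²}`. Calendar trends stratify by the
*period of diagnosis* (the natural choice when the question is whether
newly diagnosed patients fare better); true period life tables — slicing
observation time rather than diagnosis time — are a different estimand and
out of scope. Years of life lost sum, over deaths, a reference remaining
life expectancy at the band of the age at death, with no discounting or
age-weighting; the default reference is the published 2015 Iranian
general-population row (`iran_reference_2015()`), configurable to any
per-band table. Ecological correlations are plain Pearson correlations of
group-level aggregates.

## The synthetic-data generator

Because real registry extracts cannot be shipped, validation rests on
`simulate_cohort()`, which emulates the structure of a national
case-registry cohort:

* diagnosis dates uniform over a multi-decade enrollment window
  (1986-01-01 to 2016-12-30 by default), with administrative censoring at
  the study end;
* entry ages drawn from a banded distribution shaped like a national HIV
  registry — about 86% entering at ages 20–44, a thin tail through the
  fifties and a small mass (0.9%) entering the open band, which keeps
  every band, including 65+, populated at moderate cohort sizes;
* death times from the piecewise-exponential age hazard (baseline
  0.04/yr in every band) multiplied by per-person covariate hazard
  ratios; sampling is by exact inversion of the cumulative hazard, so the
  generator and the analytic oracle `true_life_expectancy()` describe the
  same law;
* loss to follow-up as an independent exponential (0.02/yr by default);
* optional missingness in sex and age, applied last.

One root seed drives a single vectorised draw sequence, so an identical
seed reproduces the cohort byte for byte; the generator also restores the
caller's RNG state. The defaults are the package's reference validation
conditions; `demo_config()` layers qualitative registry-style covariates
(a transmission mix dominated by injection drug use, ~34% treated with
hazard ratio 0.3, a small TB-positive fraction with hazard ratio 2, a few
percent missingness) for demonstrations.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real registries: informative censoring (loss to
follow-up correlated with prognosis), under-registration of deaths,
record-linkage errors, hazards varying with calendar time or with time
since diagnosis rather than age, and covariate-dependent enrollment.
Real-data results inherit those caveats.

## Problem sizes and numerical choices

The test and acceptance workloads use cohorts of 50,000 for point-recovery
checks (Monte-Carlo error ≈ 0.3 years at e ≈ 25, comfortably inside the 2%
recovery band), 500 replicates of 5,000 for coverage and variance
calibration, and 1,000 random records for the day-grid oracle comparison;
together they run in well under a minute on a single core. Dates are
required to be ISO-8601 — a column mapping can rename headers but not
introduce other date dialects, eliminating silent day/month ambiguity.
Unparseable cells become missing values that the filter must then account
for, never silent guesses. All randomness (imputation, simulation) is
explicitly seeded; there are no hidden RNG draws.

## Known limitations

* Single imputation understates (slightly) the uncertainty attributable
  to missing sex/age.
* The `a = 0.5` convention biases `e` by a fraction of a percent when the
  true hazard changes sharply at band edges; `a` is configurable per band
  if external information warrants it.
* The two-sample z-test treats strata as independent, which is exact for
  a partition but approximate for overlapping contrasts.
* The terminal-variance extension assumes a Poisson terminal death count;
  for very small `D_w` the normal interval for `e` near the open band is
  optimistic.
* No smoothing or graduation of rates is offered; sparse bands should be
  merged via the schema instead.
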