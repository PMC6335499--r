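# cohortlife

Life expectancy of a patient cohort, estimated from individual follow-up
records with Chiang's abridged life-table method.

## The problem

Registry-based cohort studies (HIV surveillance registries, cancer
registries, linked death-registration data) record, for each patient, a
diagnosis date, an age at diagnosis, an exit date, and a vital status
(death, loss to follow-up, or administrative censoring at the end of the
study). A standard way to summarise survival in such a cohort is the
**abridged (bridge) life table**: follow-up time is split across 5-year age
bands (20–24 … 60–64, plus an open 65+ band), deaths `D_j` and person-years
`PY_j` are accumulated per band, and life expectancy at each band start is
derived from the age-specific mortality rates. `cohortlife` implements that
pipeline end to end for epidemiologists who have individual-level records
and want stratified, trend, and comparison estimates with honest sampling
uncertainty.

## The method

Per age band `j` of width `n_j`:

- mortality rate: `m_j = D_j / PY_j` (person-years from an exact Lexis
  split of each subject's `[entry age, exit age)` interval; subjects are
  left-truncated at their age at diagnosis);
- probability of dying (Chiang's conversion, with `a_j` the average
  fraction of the interval lived by those dying in it, 0.5 by default):

      q_j = n_j m_j / (1 + n_j (1 − a_j) m_j)

- synthetic-cohort propagation from radix `l_1`:
  `l_{j+1} = l_j (1 − q_j)`, `d_j = l_j q_j`,
  `L_j = n_j (l_{j+1} + a_j d_j)`, `T_j = Σ_{k≥j} L_k`, `e_j = T_j / l_j`;
  the open terminal band uses `q_w = 1`, `L_w = l_w / m_w`, `e_w = 1/m_w`.

The sampling variance of `e` is Chiang's:

    S²(p_j) = q_j² p_j / D_j
    S²(e_i) = (1/l_i²) Σ_{j=i}^{w−1} l_j² [(1−a_j) n_j + e_{j+1}]² S²(p_j)
              + (l_w/l_i)² / (m_w² D_w)

where the last term is a delta-method extension for the open band (a
Poisson death count behind `e_w = 1/m_w`), and 95% limits are `e ± 1.96·SE`.

Around the core, the package provides cohort CSV loading with column
mapping, a seeded hot-deck imputer for missing sex/age (refusing to run
above 10% missingness), the eligibility filter used in registry analyses
(diagnosis date present and strictly before death, age ≥ 20) with a
deterministic exclusion report, stratified life tables, calendar-period
trends, two-group z-tests, years-of-life-lost tallies against a reference
life table, ecological correlations, and a synthetic registry-cohort
generator with piecewise-exponential ground truth for validation.

## Worked example

```r
library(cohortlife)

# A registry-style cohort with known ground truth: constant death hazard
# 0.04/yr (so true e(20) = 25 years), loss to follow-up 0.02/yr,
# enrollment 1986-2016 with administrative censoring at the study end.
cfg <- synthetic_config(n = 20000, seed = 11)
coh <- simulate_cohort(cfg)

ex <- aggregate_exposure(coh)   # deaths and person-years per age band
crude_mortality_rate(ex)
#> [1] 38.87736

lt <- build_life_table(ex)
lt
#> Chiang abridged life table (radix 100000)
#>   e(20) = 25.2 years (95% CI, 24.3 to 26.1)
#>   band deaths person_years       m      q      l      L       T     e   se_e ...
#>  20-24    183         4456 0.04106 0.1862 100000 453400 2519000 25.19 0.4612
#>  25-29    651        16700 0.03897 0.1776  81380 370800 2065000 25.38 0.3744
#>  ...
#>    65+    380         9057 0.04196 1.0000  17410 414900  414900 23.83 1.2230

true_life_expectancy(cfg$hazards)
#> [1] 25
```

The estimate `e(20) = 25.2 (24.3–26.1)` recovers the analytic truth of 25
years: the crude mortality rate of 38.9 per 1,000 person-years reflects the
0.04/yr hazard, and the interval covers the truth as it should about 95% of
the time.

A stratified contrast (treatment with hazard ratio 0.3 in a third of the
cohort):

```r
cfg2 <- synthetic_config(n = 20000, seed = 5,
  covariates = list(treatment = list(levels = c("yes", "no"),
                                     probs = c(0.34, 0.66), hr = c(0.3, 1))))
strat <- stratified_life_tables(simulate_cohort(cfg2), "treatment")
compare_life_expectancy(strat$tables$yes, strat$tables$no)
#> e(20): 90.28 vs 24.95  (treatment=yes vs treatment=no)
#>   diff = 65.33 years, SE = 7.930, z = 8.24, p = 1.76e-16
```

For file-based work, `run_pipeline()` drives the whole analysis (load →
impute → filter → exposure → life tables → strata/trend) from a YAML or
list configuration and writes life-table CSVs, a summary CSV, an exclusion
report (JSON) and a text report; `inst/cli/cohortlife.R` is a thin
command-line wrapper with `simulate` and `build` subcommands.

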