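schema10 <- age_band_schema()

test_that("a constant covariate reproduces the pooled life table", {
  coh <- simulate_cohort(synthetic_config(n = 6000, seed = 13))
  coh$records$site <- "clinic_a"
  res <- stratified_life_tables(coh, "site", schema10)
  expect_equal(names(res$tables), "clinic_a")
  pooled <- build_life_table(aggregate_exposure(coh, schema10))
  expect_equal(res$tables$clinic_a$e, pooled$e, tolerance = 1e-12)
  expect_equal(res$tables$clinic_a$se_e, pooled$se_e, tolerance = 1e-12)
})

test_that("strata partition the cohort's exposure", {
  cfg <- demo_config(n = 4000, seed = 23)
  coh <- simulate_cohort(cfg)
  coh <- impute_missing(coh, seed = 2)
  res <- suppressWarnings(stratified_life_tables(coh, "transmission", schema10))
  py_sum <- Reduce(`+`, lapply(res$exposures, function(e) e$person_years))
  expect_equal(py_sum, res$pooled$person_years, tolerance = 1e-9)
  d_sum <- Reduce(`+`, lapply(res$exposures, function(e) e$deaths))
  expect_equal(d_sum, res$pooled$deaths)
  # missing covariate values form their own stratum rather than vanishing
  coh$records$transmission[1:25] <- NA
  res2 <- suppressWarnings(stratified_life_tables(coh, "transmission", schema10))
  expect_true("unknown" %in% names(c(res2$tables, res2$failed)))
})

test_that("a hazard ratio of 3 lowers life expectancy at every age", {
  cfg <- synthetic_config(
    n = 30000, seed = 33,
    covariates = list(risk = list(levels = c("low", "high"),
                                  probs = c(0.5, 0.5), hr = c(1, 3)))
  )
  res <- suppressWarnings(
    stratified_life_tables(simulate_cohort(cfg), "risk", schema10))
  expect_true(all(res$tables$high$e < res$tables$low$e))
})

test_that("insufficient strata are reported as failed, not dropped", {
  coh <- simulate_cohort(synthetic_config(n = 3000, seed = 43))
  # a tiny stratum with no terminal deaths fails with the builder's reason
  coh$records$grp <- c("tiny", rep("main", nrow(coh$records) - 1L))
  res <- stratified_life_tables(coh, "grp", schema10)
  expect_true("main" %in% names(res$tables))
  expect_true("tiny" %in% names(res$failed))
  expect_match(res$failed[["tiny"]], "band")
  expect_error(stratified_life_tables(coh, "nope", schema10), "not found")
})

test_that("the two-group z-test behaves like a z-test", {
  coh <- simulate_cohort(synthetic_config(n = 6000, seed = 13))
  lt <- build_life_table(aggregate_exposure(coh, schema10))
  same <- compare_life_expectancy(lt, lt)
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)

  cfg <- synthetic_config(
    n = 20000, seed = 53,
    covariates = list(art = list(levels = c("yes", "no"),
                                 probs = c(0.4, 0.6), hr = c(0.35, 1)))
  )
  res <- suppressWarnings(
    stratified_life_tables(simulate_cohort(cfg), "art", schema10))
  cmp <- compare_life_expectancy(res$tables$yes, res$tables$no)
  expect_gt(cmp$diff, 0)
  expect_lt(cmp$p_value, 0.001)
  # antisymmetry
  rev <- compare_life_expectancy(res$tables$no, res$tables$yes)
  expect_equal(rev$diff, -cmp$diff)
  expect_equal(rev$z, -cmp$z)
  expect_equal(rev$p_value, cmp$p_value)

  schema_other <- age_band_schema(starts = c(20, 40, 60))
  lt_other <- build_life_table(
    exposure_table(c(50, 50, 50), c(1000, 1000, 500), schema_other)
  )
  expect_error(compare_life_expectancy(lt, lt_other), "schema")
})

test_that("published-summary contrasts reconstruct the reported significance", {
  # treated 37.0 (36.2-37.8) vs untreated 15.5 (15.1-15.9)
  cmp <- compare_from_summaries(37.0, 36.2, 37.8, 15.5, 15.1, 15.9)
  expect_equal(cmp$se, sqrt((1.6 / 3.92)^2 + (0.8 / 3.92)^2), tolerance = 1e-12)
  expect_gt(cmp$z, 40)
  expect_lt(cmp$p_value, 0.001)
})

test_that("period trend stratifies by diagnosis period and tracks hazard changes", {
  early <- synthetic_config(
    n = 6000, seed = 63, hazards = rep(0.06, 10),
    enrollment_start = "1986-01-01", enrollment_end = "2000-12-31"
  )
  late <- synthetic_config(
    n = 6000, seed = 64, hazards = rep(0.042, 10),  # 30% lower
    enrollment_start = "2001-01-01", enrollment_end = "2016-12-30"
  )
  r1 <- simulate_cohort(early)$records
  r2 <- simulate_cohort(late)$records
  r2$person_id <- paste0("L", r2$person_id)
  coh <- cohort(rbind(r1, r2), study_end = as.Date("2016-12-30"))

  res <- suppressWarnings(period_trend(coh, c(1986, 2001, 2017), schema10))
  expect_equal(names(res$tables), c("1986-2000", "2001-2016"))
  expect_gt(res$tables[["2001-2016"]]$e[1], res$tables[["1986-2000"]]$e[1])
  # periods partition the cohort
  py <- sum(vapply(res$exposures, function(e) sum(e$person_years), numeric(1)))
  expect_equal(py, sum(res$pooled$person_years), tolerance = 1e-9)
})

test_that("a stationary simulator shows no period effect beyond noise", {
  coh <- simulate_cohort(synthetic_config(n = 20000, seed = 73))
  res <- suppressWarnings(period_trend(coh, c(1986, 2001, 2017), schema10))
  e <- vapply(res$tables, function(t) t$e[1], numeric(1))
  se <- vapply(res$tables, function(t) t$se_e[1], numeric(1))
  expect_lt(abs(e[1] - e[2]), 4 * sqrt(sum(se^2)))
})

test_that("years of life lost sums the reference expectancy over deaths", {
  expect_equal(
    years_of_life_lost(
      make_cohort(rec("a", 30, 100, "died")),
      reference_e = rep(0, 10)
    ), 0)
  # one death at an age in 30-34 against the national reference row
  yll <- years_of_life_lost(make_cohort(rec("a", 30, 100, "died")))
  expect_equal(yll, 46.8)
  # additivity over any partition
  df <- random_records(120, seed = 83)
  whole <- years_of_life_lost(cohort(df))
  half1 <- years_of_life_lost(cohort(df[1:60, ]))
  half2 <- years_of_life_lost(cohort(df[61:120, ]))
  expect_equal(whole, half1 + half2, tolerance = 1e-9)
  expect_error(
    years_of_life_lost(make_cohort(rec("a", 30, 100, "died")),
                       reference_e = rep(10, 3)),
    "one value per band"
  )
})

test_that("ecological correlation handles exact and degenerate cases", {
  e <- c(31.4, 25.0, 19.9, 13.2, 23.8)
  expect_equal(ecological_correlation(e, 2 * e + 3), 1.0)
  expect_equal(ecological_correlation(e, -e), -1.0)
  expect_error(ecological_correlation(e, rep(1, 5)), "constant")
  expect_error(ecological_correlation(e[1:2], e[1:2]), "3 paired groups")
  # independent covariate across 28 groups rarely fakes a strong correlation
  set.seed(93)
  hits <- replicate(100, {
    abs(ecological_correlation(rnorm(28, 22, 4), rnorm(28))) < 0.5
  })
  expect_gte(mean(hits), 0.95)
})
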