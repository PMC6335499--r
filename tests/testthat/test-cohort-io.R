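test_that("load_cohort parses well-formed rows and flags unparseable cells", {
  df <- rbind(
    rec("a", 25, 100, "died"),
    rec("b", 30, 200, "censored"),
    rec("c", 40, 300, "alive_at_study_end")
  )
  path <- write_fixture_csv(df)
  coh <- load_cohort(path)
  expect_s3_class(coh, "cohort")
  expect_equal(nrow(coh$records), 3L)
  expect_equal(coh$records$age_at_diagnosis, c(25, 30, 40))
  expect_true(any(grepl("loaded 3 rows", coh$provenance)))

  # empty diagnosis cell -> loaded with missing date (excluded later)
  df2 <- df
  df2$date_of_diagnosis <- as.character(df2$date_of_diagnosis)
  df2$date_of_diagnosis[2] <- ""
  coh2 <- load_cohort(write_fixture_csv(df2))
  expect_true(is.na(coh2$records$date_of_diagnosis[2]))

  # malformed date dialect is set to missing and logged, not guessed
  df3 <- df
  df3$date_of_diagnosis <- as.character(df3$date_of_diagnosis)
  df3$date_of_diagnosis[1] <- "01/02/2000"
  coh3 <- load_cohort(write_fixture_csv(df3))
  expect_true(is.na(coh3$records$date_of_diagnosis[1]))
  expect_true(any(grepl("unparseable date_of_diagnosis", coh3$provenance)))
})

test_that("load_cohort fatal errors: missing file, zero rows, unknown status", {
  expect_error(load_cohort(file.path(tempdir(), "no-such-file.csv")), "not found")

  header_only <- tempfile(fileext = ".csv")
  writeLines("person_id,sex,date_of_diagnosis,age_at_diagnosis,exit_date,status",
             header_only)
  expect_error(load_cohort(header_only), "zero data rows")

  df <- rbind(rec("a", 25, 100, "died"), rec("b", 30, 200, "expired"))
  expect_error(load_cohort(write_fixture_csv(df)), "unknown status code at row 2")
})

test_that("load_cohort honours column mapping and derives age from birth date", {
  df <- data.frame(
    id = "x1", gender = "female", dx_date = "2000-01-01",
    dob = "1970-01-01", last_seen = "2005-01-01", outcome = "censored"
  )
  coh <- load_cohort(
    write_fixture_csv(df),
    mapping = c(person_id = "id", sex = "gender", date_of_diagnosis = "dx_date",
                birth_date = "dob", exit_date = "last_seen", status = "outcome")
  )
  expect_equal(coh$records$sex, "female")
  expect_equal(coh$records$age_at_diagnosis, 30, tolerance = 0.01)
  expect_error(
    load_cohort(write_fixture_csv(df), mapping = c(person_id = "id")),
    "mandatory column not mappable"
  )
})

test_that("eligibility filter applies reasons in fixed precedence", {
  diag <- as.Date("2000-06-01")
  df <- rbind(
    rec("keep", 25, 500, "died"),
    rec("no_diag", 25, 500, "died"),
    rec("same_day_death", 25, 0, "died"),
    rec("death_before_diag", 25, -10, "died"),
    rec("too_young", 19.4, 500, "censored"),
    rec("zero_len_censored", 30, 0, "censored"),
    rec("bad_interval", 30, -5, "censored")
  )
  df$date_of_diagnosis[df$person_id == "no_diag"] <- NA
  coh <- cohort(df, study_end = as.Date("2010-01-01"))
  out <- filter_eligible(coh)

  expect_setequal(out$cohort$records$person_id, c("keep", "zero_len_censored"))
  rep <- out$report
  got <- setNames(rep$excluded$reason, rep$excluded$person_id)
  expect_equal(got[["no_diag"]], "missing_diagnosis_date")
  expect_equal(got[["same_day_death"]], "diagnosis_not_before_death")
  expect_equal(got[["death_before_diag"]], "diagnosis_not_before_death")
  expect_equal(got[["too_young"]], "under_age_minimum")
  expect_equal(got[["bad_interval"]], "malformed_record")

  # a record tripping several reasons is excluded once, under the first
  df2 <- rec("multi", 18, 0, "died")
  df2$date_of_diagnosis <- NA
  out2 <- filter_eligible(cohort(rbind(rec("k", 30, 10), df2)))
  expect_equal(out2$report$excluded$reason, "missing_diagnosis_date")
  expect_gte(sum(out2$report$counts), nrow(out2$report$excluded))
})

test_that("filter conserves records, is idempotent, and passes valid cohorts through", {
  coh <- cohort(random_records(200, seed = 3))
  once <- filter_eligible(coh)
  expect_equal(nrow(coh$records),
               once$report$n_retained + nrow(once$report$excluded))

  twice <- filter_eligible(once$cohort)
  expect_equal(twice$cohort$records, once$cohort$records)
  expect_equal(nrow(twice$report$excluded), 0L)

  all_valid <- cohort(rbind(rec("a", 25, 100), rec("b", 40, 3000, "died")))
  res <- filter_eligible(all_valid)
  expect_equal(res$cohort$records, all_valid$records)
  expect_equal(sum(res$report$counts), 0L)
})

test_that("hot-deck imputation is seeded, stratified, and leaves observed values alone", {
  set.seed(42)
  df <- random_records(400, seed = 9)
  df$transmission <- sample(c("idu", "sexual"), 400, replace = TRUE)
  df$sex[df$transmission == "sexual"] <- "female"  # stratum pool is all-female
  miss_sex <- sample(which(df$transmission == "sexual"), 12)
  df$sex[miss_sex] <- NA
  miss_age <- sample(400, 20)
  df$age_at_diagnosis[miss_age] <- NA
  coh <- cohort(df)

  imp1 <- impute_missing(coh, seed = 7)
  imp2 <- impute_missing(coh, seed = 7)
  expect_identical(imp1$records, imp2$records)
  expect_false(anyNA(imp1$records$sex))
  expect_false(anyNA(imp1$records$age_at_diagnosis))

  # sex drawn from the transmission stratum's empirical distribution
  expect_true(all(imp1$records$sex[miss_sex] == "female"))
  # non-missing fields never altered
  obs <- setdiff(seq_len(400), union(miss_sex, miss_age))
  expect_identical(imp1$records[obs, ], coh$records[obs, ])
})

test_that("imputation refuses to run above the missingness threshold", {
  df <- random_records(100, seed = 4)
  df$age_at_diagnosis[1:12] <- NA
  expect_error(impute_missing(cohort(df), seed = 1), "0\\.12 > 0\\.1")

  df2 <- random_records(50, seed = 5)
  coh2 <- cohort(df2)
  expect_identical(impute_missing(coh2, seed = 1), coh2)  # nothing missing
  expect_error(impute_missing(coh2), "seed")
})

test_that("exclusion reports serialize to JSON", {
  coh <- cohort(rbind(rec("a", 25, 100), rec("b", 15, 100)))
  out <- filter_eligible(coh)
  path <- tempfile(fileext = ".json")
  write_exclusion_report(out$report, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n_retained, 1L)
  expect_equal(parsed$excluded[[1]]$reason, "under_age_minimum")
})
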