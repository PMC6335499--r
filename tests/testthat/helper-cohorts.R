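# Fixture builders: small cohorts assembled in code, no stored data.

# One record with an exact entry age and a follow-up duration in whole days
# (Date arithmetic is integer days, so durations in days keep ages exact).
rec <- function(id, entry_age, dur_days, status = "censored", sex = "male",
                diagnosis = as.Date("2000-01-01"), ...) {
  data.frame(
    person_id = id, sex = sex,
    date_of_diagnosis = diagnosis,
    age_at_diagnosis = entry_age,
    exit_date = diagnosis + dur_days,
    status = status,
    ...,
    stringsAsFactors = FALSE
  )
}

make_cohort <- function(..., study_end = NULL) {
  cohort(do.call(rbind, list(...)), study_end = study_end)
}

years_of <- function(days) days / 365.2425

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Random eligible records for property-style checks.
random_records <- function(n, seed) {
  set.seed(seed)
  diagnosis <- as.Date("1990-01-01") + sample.int(9000L, n, replace = TRUE)
  dur <- sample.int(30L * 365L, n, replace = TRUE)
  data.frame(
    person_id = sprintf("R%05d", seq_len(n)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    date_of_diagnosis = diagnosis,
    age_at_diagnosis = runif(n, 20, 72),
    exit_date = diagnosis + dur,
    status = sample(c("died", "censored", "alive_at_study_end"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
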