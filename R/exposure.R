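# Lexis splitting of follow-up across age bands and exposure aggregation.
#
# Ages are exact real years (days / 365.2425); bands are half-open
# [start, start + width), so a death at exactly a boundary age falls in the
# higher band. Follow-up starts at diagnosis (left truncation): no exposure
# is counted below the entry age.

# Vectorised core: person-years contributed by each (entry, exit) interval to
# each band. Returns an n x w matrix.
band_py_matrix <- function(entry_age, exit_age, schema) {
  w <- nrow(schema)
  lo <- schema$start
  hi <- schema$start + schema$width
  out <- matrix(0, length(entry_age), w)
  for (j in seq_len(w)) {
    out[, j] <- pmax(0, pmin(exit_age, hi[j]) - pmax(entry_age, lo[j]))
  }
  out
}

#' Split one person's follow-up across age bands
#'
#' Allots the follow-up interval `[entry_age, exit_age)` to the age bands it
#' intersects; the allotted person-years sum to `exit_age - entry_age`
#' exactly. If the person died, the death is assigned to the band containing
#' the exact exit age (half-open convention).
#'
#' A censored record with `exit_age == entry_age` is legal and contributes
#' zero person-years; a death requires strictly positive follow-up.
#'
#' @param entry_age Exact age at entry (years); at or above the first band
#'   start.
#' @param exit_age Exact age at exit (years); `>= entry_age`.
#' @param died Logical: did follow-up end in death?
#' @param schema An [age_band_schema()].
#' @return A list with `person_years` (named numeric, one per band) and
#'   `death_band` (band index, or `NA` if censored).
#' @export
split_person_years <- function(entry_age, exit_age, died = FALSE,
                               schema = age_band_schema()) {
  stopifnot(length(entry_age) == 1L, length(exit_age) == 1L)
  if (is.na(entry_age) || is.na(exit_age)) stop("entry and exit ages must be known")
  if (entry_age < schema$start[1]) {
    stop(sprintf("entry age %.3f below first band start %g (record should have been filtered)",
                 entry_age, schema$start[1]))
  }
  if (exit_age < entry_age) stop("exit age precedes entry age")
  if (died && exit_age <= entry_age) stop("death requires exit age > entry age")
  py <- drop(band_py_matrix(entry_age, exit_age, schema))
  names(py) <- band_labels(schema)
  list(
    person_years = py,
    death_band = if (died) band_index(exit_age, schema) else NA_integer_
  )
}

#' Aggregate deaths and person-years per age band
#'
#' Runs the Lexis split over every record of an eligible, complete cohort and
#' sums deaths `D_j` and person-years `PY_j` per band: the sufficient
#' statistics for the abridged life table. Entry age is the age at diagnosis;
#' exit age is entry age plus the elapsed calendar follow-up in exact years.
#'
#' @param cohort A [cohort()] whose records are eligible and complete (no
#'   missing ages or dates).
#' @param schema An [age_band_schema()].
#' @param group_label Optional stratum name carried along for reporting.
#' @return An `exposure_table`: a data frame with one row per band and
#'   columns `band`, `band_start`, `band_width`, `a`, `deaths`,
#'   `person_years`; the schema and label travel as attributes.
#' @export
aggregate_exposure <- function(cohort, schema = age_band_schema(),
                               group_label = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  r <- cohort$records
  w <- nrow(schema)
  if (nrow(r) == 0L) {
    return(new_exposure_table(integer(w), numeric(w), schema, group_label))
  }
  if (anyNA(r$age_at_diagnosis) || anyNA(r$date_of_diagnosis) || anyNA(r$exit_date)) {
    stop("cohort has missing ages or dates; run impute_missing()/filter_eligible() first")
  }
  entry <- r$age_at_diagnosis
  exit <- entry + years_between(r$date_of_diagnosis, r$exit_date)
  if (any(entry < schema$start[1])) {
    stop("entry age below first band start; records should have been filtered")
  }
  if (any(exit < entry)) stop("exit date precedes diagnosis date")
  died <- r$status == "died"
  if (any(died & exit <= entry)) {
    stop("death with non-positive follow-up; records should have been filtered")
  }
  n_zero <- sum(!died & exit == entry)
  if (n_zero > 0L) {
    warning(sprintf("%d censored record(s) with zero-length follow-up contribute 0 person-years",
                    n_zero))
  }

  py <- colSums(band_py_matrix(entry, exit, schema))
  db <- band_index(exit[died], schema)
  deaths <- tabulate(db, nbins = w)
  new_exposure_table(deaths, py, schema, group_label)
}

#' Assemble an exposure table from band-level counts
#'
#' For data that arrive already aggregated (deaths and person-years per age
#' band) rather than as individual records.
#'
#' @param deaths Non-negative integer deaths per band.
#' @param person_years Non-negative person-years per band.
#' @param schema An [age_band_schema()] with one band per entry.
#' @param group_label Optional stratum name.
#' @return An `exposure_table`.
#' @export
exposure_table <- function(deaths, person_years, schema = age_band_schema(),
                           group_label = NULL) {
  w <- nrow(schema)
  if (length(deaths) != w || length(person_years) != w) {
    stop("deaths and person_years must have one entry per band")
  }
  if (any(deaths < 0) || any(person_years < 0)) {
    stop("deaths and person_years must be non-negative")
  }
  new_exposure_table(deaths, person_years, schema, group_label)
}

new_exposure_table <- function(deaths, person_years, schema, group_label = NULL) {
  out <- data.frame(
    band = band_labels(schema),
    band_start = schema$start,
    band_width = schema$width,
    a = schema$a,
    deaths = as.integer(deaths),
    person_years = as.numeric(person_years)
  )
  attr(out, "schema") <- schema
  attr(out, "group_label") <- group_label
  class(out) <- c("exposure_table", "data.frame")
  out
}

#' @export
print.exposure_table <- function(x, digits = 2, ...) {
  lbl <- attr(x, "group_label")
  cat(sprintf("Exposure table%s: %d deaths over %.1f person-years\n",
              if (is.null(lbl)) "" else paste0(" [", lbl, "]"),
              sum(x$deaths), sum(x$person_years)))
  df <- as.data.frame(x)
  df$person_years <- round(df$person_years, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Crude mortality rate
#'
#' Total deaths divided by total person-years, scaled to a conventional
#' denominator (per 1,000 person-years by default).
#'
#' @param exposure An `exposure_table` from [aggregate_exposure()].
#' @param per Scaling denominator (default 1000).
#' @return The crude mortality rate per `per` person-years.
#' @export
crude_mortality_rate <- function(exposure, per = 1000) {
  stopifnot(inherits(exposure, "exposure_table"))
  total_py <- sum(exposure$person_years)
  if (total_py <= 0) stop("zero total person-years; crude rate undefined")
  per * sum(exposure$deaths) / total_py
}

#' Write an exposure table to CSV
#'
#' @param exposure An `exposure_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(exposure, path) {
  utils::write.csv(as.data.frame(exposure), path, row.names = FALSE)
  invisible(path)
}
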