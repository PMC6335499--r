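#' Construct a cohort object
#'
#' A cohort bundles one row per subject (the follow-up interval, vital
#' status, and covariates) with the administrative end of study and an audit
#' trail of how the object was produced.
#'
#' @param records Data frame with canonical columns `person_id`, `sex`
#'   (`"male"`/`"female"`/`NA`), `date_of_diagnosis` (`Date`),
#'   `age_at_diagnosis` (years), `exit_date` (`Date`), `status`
#'   (`"died"`, `"censored"`, `"alive_at_study_end"`), plus any number of
#'   covariate columns.
#' @param study_end `Date` of administrative censoring; defaults to the
#'   latest exit date.
#' @param provenance Character vector of audit notes.
#' @return An object of class `cohort`.
#' @export
cohort <- function(records, study_end = NULL, provenance = character()) {
  stopifnot(is.data.frame(records))
  needed <- c("person_id", "sex", "date_of_diagnosis", "age_at_diagnosis",
              "exit_date", "status")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records lack canonical column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(records$person_id)) {
    stop("person_id values must be unique")
  }
  bad_status <- !records$status %in% c("died", "censored", "alive_at_study_end")
  if (any(bad_status)) {
    stop("unknown status code at row ", which(bad_status)[1],
         ": '", records$status[which(bad_status)[1]], "'")
  }
  if (is.null(study_end)) study_end <- max(records$exit_date, na.rm = TRUE)
  study_end <- as.Date(study_end)
  if (any(records$exit_date > study_end, na.rm = TRUE)) {
    stop("study_end precedes some exit dates")
  }
  structure(
    list(records = records, study_end = study_end, provenance = provenance),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("Cohort: %d records, study end %s\n", nrow(r), format(x$study_end)))
  cat(sprintf("  status: %s\n",
              paste(sprintf("%s=%d", names(table(r$status)), table(r$status)),
                    collapse = ", ")))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    cat(paste0("   - ", x$provenance, collapse = "\n"), "\n")
  }
  invisible(x)
}

covariate_names <- function(cohort) {
  setdiff(names(cohort$records),
          c("person_id", "sex", "date_of_diagnosis", "birth_date",
            "age_at_diagnosis", "exit_date", "status"))
}

#' Read a cohort from a delimited file
#'
#' Reads a UTF-8 comma-separated file with a header row into a [cohort()].
#' Dates must be ISO-8601 (`YYYY-MM-DD`); cells that fail to parse as a date
#' or number are set to missing and noted in the provenance, so that the
#' eligibility filter can account for them explicitly. If `age_at_diagnosis`
#' is absent or missing but `birth_date` is present, age at diagnosis is
#' derived from the two dates.
#'
#' @param path Path to the CSV file.
#' @param mapping Optional named character vector or list mapping canonical
#'   column names to the file's header names (e.g.
#'   `c(person_id = "id", exit_date = "last_visit")`), or the path to a YAML
#'   file holding such a mapping. Unmapped canonical names are looked up
#'   verbatim.
#' @param study_end Optional administrative end of study (`Date` or
#'   ISO-8601 string); defaults to the latest exit date in the file.
#' @return A [cohort()]; every data row becomes one record.
#' @export
load_cohort <- function(path, mapping = NULL, study_end = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping) &&
      grepl("\\.ya?ml$", mapping)) {
    mapping <- yaml::read_yaml(mapping)
  }
  mapping <- unlist(mapping)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("zero data rows in ", path)

  pick <- function(canon) {
    src <- if (!is.null(mapping) && canon %in% names(mapping)) mapping[[canon]] else canon
    if (src %in% names(raw)) raw[[src]] else NULL
  }
  for (canon in c("person_id", "exit_date", "status")) {
    if (is.null(pick(canon))) stop("mandatory column not mappable: ", canon)
  }

  n <- nrow(raw)
  notes <- character()
  log_bad <- function(what, bad) {
    if (any(bad)) {
      notes <<- c(notes, sprintf("%d unparseable %s value(s) set to missing (rows %s)",
                                 sum(bad), what,
                                 paste(utils::head(which(bad), 5L), collapse = ",")))
    }
  }

  diag_raw <- pick("date_of_diagnosis") %||% rep(NA_character_, n)
  diag <- parse_iso_date(diag_raw)
  log_bad("date_of_diagnosis", is.na(diag) & !is.na(diag_raw) & nzchar(trimws(diag_raw)))

  exit_raw <- pick("exit_date")
  exit <- parse_iso_date(exit_raw)
  log_bad("exit_date", is.na(exit) & !is.na(exit_raw) & nzchar(trimws(exit_raw)))

  birth <- parse_iso_date(pick("birth_date") %||% rep(NA_character_, n))

  age_raw <- pick("age_at_diagnosis") %||% rep(NA_character_, n)
  age <- parse_num(age_raw)
  log_bad("age_at_diagnosis", is.na(age) & !is.na(age_raw) & nzchar(trimws(age_raw)))
  derive <- is.na(age) & !is.na(birth) & !is.na(diag)
  age[derive] <- years_between(birth[derive], diag[derive])

  sex <- tolower(trimws(pick("sex") %||% rep(NA_character_, n)))
  sex[!sex %in% c("male", "female")] <- NA_character_

  status <- tolower(trimws(pick("status")))
  status[!nzchar(status)] <- NA_character_
  bad_status <- is.na(status) | !status %in% c("died", "censored", "alive_at_study_end")
  if (any(bad_status)) {
    stop("unknown status code at row ", which(bad_status)[1],
         ": '", pick("status")[which(bad_status)[1]], "'")
  }

  canonical_src <- vapply(
    c("person_id", "sex", "date_of_diagnosis", "birth_date", "age_at_diagnosis",
      "exit_date", "status"),
    function(canon) {
      if (!is.null(mapping) && canon %in% names(mapping)) mapping[[canon]] else canon
    }, character(1)
  )
  covar <- raw[, setdiff(names(raw), canonical_src), drop = FALSE]

  records <- data.frame(
    person_id = pick("person_id"),
    sex = sex,
    date_of_diagnosis = diag,
    age_at_diagnosis = age,
    exit_date = exit,
    status = status,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, covar)

  cohort(
    records,
    study_end = if (is.null(study_end)) NULL else as.Date(study_end),
    provenance = c(sprintf("loaded %d rows from %s", n, path), notes)
  )
}

exclusion_reasons <- c("missing_diagnosis_date", "diagnosis_not_before_death",
                       "under_age_minimum", "malformed_record")

#' Apply the eligibility filter
#'
#' Retains records with a diagnosis date that strictly precedes death (for
#' decedents), a known, well-formed follow-up interval, and an age at
#' diagnosis of at least `min_age`. Records failing several checks are
#' excluded once, under the first failing reason in the fixed precedence
#' `missing_diagnosis_date` > `diagnosis_not_before_death` >
#' `under_age_minimum` > `malformed_record`. Censored records whose exit date
#' equals the diagnosis date are retained (they contribute zero follow-up);
#' only for deaths does that coincidence exclude.
#'
#' @param cohort A [cohort()].
#' @param min_age Minimum age at diagnosis in years (default 20).
#' @return A list with elements `cohort` (the filtered cohort) and `report`
#'   (an `exclusion_report`: per-reason counts and the excluded ids).
#' @export
filter_eligible <- function(cohort, min_age = 20) {
  stopifnot(inherits(cohort, "cohort"))
  r <- cohort$records

  missing_diag <- is.na(r$date_of_diagnosis)
  died <- r$status == "died"
  diag_not_before_death <- !missing_diag & died &
    !is.na(r$exit_date) & r$exit_date <= r$date_of_diagnosis
  under_age <- !is.na(r$age_at_diagnosis) & r$age_at_diagnosis < min_age
  malformed <- is.na(r$exit_date) | is.na(r$age_at_diagnosis) |
    (!is.na(r$age_at_diagnosis) &
       (r$age_at_diagnosis < 0 | r$age_at_diagnosis >= 120)) |
    (!died & !missing_diag & !is.na(r$exit_date) &
       r$exit_date < r$date_of_diagnosis)

  reason_mat <- cbind(missing_diag, diag_not_before_death, under_age, malformed)
  colnames(reason_mat) <- exclusion_reasons
  excluded <- rowSums(reason_mat) > 0
  primary <- apply(reason_mat, 1L, function(z) {
    if (any(z)) exclusion_reasons[which(z)[1]] else NA_character_
  })

  counts <- colSums(reason_mat)
  report <- structure(
    list(
      counts = as.integer(counts),
      reasons = exclusion_reasons,
      excluded = data.frame(
        person_id = r$person_id[excluded],
        reason = primary[excluded],
        stringsAsFactors = FALSE
      ),
      n_input = nrow(r),
      n_retained = sum(!excluded)
    ),
    class = "exclusion_report"
  )
  names(report$counts) <- exclusion_reasons

  kept <- r[!excluded, , drop = FALSE]
  rownames(kept) <- NULL
  if (nrow(kept) == 0L) warning("eligibility filter removed every record")
  out <- cohort
  out$records <- kept
  out$provenance <- c(
    cohort$provenance,
    sprintf("eligibility filter (min_age=%g): %d in, %d retained, %d excluded",
            min_age, nrow(r), nrow(kept), sum(excluded))
  )
  list(cohort = out, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d of %d records excluded\n",
              nrow(x$excluded), x$n_input))
  tab <- table(factor(x$excluded$reason, levels = x$reasons))
  for (rs in x$reasons) {
    cat(sprintf("  %-28s %d (primary) / %d (any)\n", rs, tab[[rs]],
                x$counts[[rs]]))
  }
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An `exclusion_report` from [filter_eligible()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(
    list(
      n_input = report$n_input,
      n_retained = report$n_retained,
      counts_any_reason = as.list(report$counts),
      excluded = report$excluded
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Impute missing sex and age by seeded hot-deck
#'
#' Fills missing `sex` and `age_at_diagnosis` by drawing from the observed
#' empirical distributions: sex from the distribution within the same
#' transmission-route category (overall if no `transmission` column or the
#' stratum has no observed sex), then age from the observed ages within the
#' record's (possibly just-imputed) sex, falling back to all observed ages.
#' This is a deliberately simple, fully reproducible single imputation that
#' preserves marginals; it does not propagate imputation uncertainty the way
#' a multiple-imputation procedure would.
#'
#' Imputation refuses to run when either variable is missing in more than
#' `max_missing_fraction` of records, mirroring the applicability condition
#' under which single imputation of these registries is defensible.
#'
#' @param cohort A [cohort()].
#' @param seed Integer seed; identical seed and input give identical output.
#' @param max_missing_fraction Maximum tolerated missing fraction per
#'   variable (default 0.10).
#' @return The completed [cohort()]; non-missing fields are never altered.
#' @export
impute_missing <- function(cohort, seed, max_missing_fraction = 0.10) {
  stopifnot(inherits(cohort, "cohort"))
  if (missing(seed)) stop("an explicit seed is required")
  r <- cohort$records
  if (nrow(r) == 0L) return(cohort)

  frac_sex <- mean(is.na(r$sex))
  frac_age <- mean(is.na(r$age_at_diagnosis))
  if (frac_sex > max_missing_fraction) {
    stop(sprintf("missing fraction of sex is %.4g > %.4g; imputation not applicable",
                 frac_sex, max_missing_fraction))
  }
  if (frac_age > max_missing_fraction) {
    stop(sprintf("missing fraction of age_at_diagnosis is %.4g > %.4g; imputation not applicable",
                 frac_age, max_missing_fraction))
  }
  n_sex <- sum(is.na(r$sex))
  n_age <- sum(is.na(r$age_at_diagnosis))
  if (n_sex + n_age == 0L) return(cohort)

  with_seed(seed, {
    if (n_sex > 0L) {
      strat <- if ("transmission" %in% names(r)) as.character(r$transmission)
               else rep("all", nrow(r))
      strat[is.na(strat)] <- "unknown"
      for (i in which(is.na(r$sex))) {
        pool <- r$sex[!is.na(r$sex) & strat == strat[i]]
        if (!length(pool)) pool <- r$sex[!is.na(r$sex)]
        if (!length(pool)) stop("no observed sex values to impute from")
        r$sex[i] <- sample(pool, 1L)
      }
    }
    if (n_age > 0L) {
      for (i in which(is.na(r$age_at_diagnosis))) {
        pool <- r$age_at_diagnosis[!is.na(r$age_at_diagnosis) & r$sex == r$sex[i]]
        if (!length(pool)) pool <- r$age_at_diagnosis[!is.na(r$age_at_diagnosis)]
        if (!length(pool)) stop("no observed ages to impute from")
        r$age_at_diagnosis[i] <- sample(pool, 1L)
      }
    }
  })

  out <- cohort
  out$records <- r
  out$provenance <- c(
    cohort$provenance,
    sprintf("hot-deck imputation (seed=%d): %d sex, %d age values imputed",
            as.integer(seed), n_sex, n_age)
  )
  out
}

#' Write a cohort to the canonical CSV layout
#'
#' @param cohort A [cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort$records, path, row.names = FALSE, na = "")
  invisible(path)
}
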