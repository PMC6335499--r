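# Stratified life tables, group contrasts, period trends, years of life
# lost, and ecological (group-level) correlation.

#' Life tables stratified by a covariate
#'
#' Splits the cohort by one covariate (missing values form an `"unknown"`
#' stratum, so the strata always partition the cohort), aggregates exposure
#' and builds a life table per stratum. Strata where the life table cannot be
#' built (e.g. no terminal deaths, empty bands) are reported as failed with
#' the reason rather than silently dropped.
#'
#' @param cohort A [cohort()] of eligible, complete records.
#' @param by Name of a covariate column (or `"sex"`).
#' @param schema An [age_band_schema()].
#' @param radix,terminal_e_fixed Passed to [build_life_table()].
#' @return A `stratified_result`: list with `by`, `tables` (named list of
#'   `life_table`), `exposures` (named list of `exposure_table`), `failed`
#'   (named character vector of reasons), and `pooled` (the whole-cohort
#'   `exposure_table`).
#' @export
stratified_life_tables <- function(cohort, by, schema = age_band_schema(),
                                   radix = 1e5, terminal_e_fixed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (!by %in% names(cohort$records)) {
    stop("covariate not found in cohort: ", by)
  }
  values <- as.character(cohort$records[[by]])
  values[is.na(values) | !nzchar(values)] <- "unknown"
  strata <- sort(unique(values))

  tables <- list()
  exposures <- list()
  failed <- character()
  for (s in strata) {
    sub <- cohort
    sub$records <- cohort$records[values == s, , drop = FALSE]
    ex <- aggregate_exposure(sub, schema, group_label = paste0(by, "=", s))
    exposures[[s]] <- ex
    lt <- tryCatch(
      build_life_table(ex, radix = radix, terminal_e_fixed = terminal_e_fixed),
      error = function(e) conditionMessage(e)
    )
    if (inherits(lt, "life_table")) tables[[s]] <- lt else failed[[s]] <- lt
  }
  if (length(tables) == 0L) {
    stop("life table failed in every stratum of '", by, "': ",
         paste(failed, collapse = " | "))
  }
  structure(
    list(
      by = by,
      tables = tables,
      exposures = exposures,
      failed = failed,
      pooled = aggregate_exposure(cohort, schema, group_label = "pooled")
    ),
    class = "stratified_result"
  )
}

#' @export
print.stratified_result <- function(x, ...) {
  cat(sprintf("Stratified life tables by '%s' (%d strata, %d failed)\n",
              x$by, length(x$tables) + length(x$failed), length(x$failed)))
  for (s in names(x$tables)) {
    lt <- x$tables[[s]]
    cat(sprintf("  %-20s e(%g) = %5.1f (95%% CI, %.1f to %.1f)  [%d deaths / %.0f py]\n",
                s, lt$x[1], lt$e[1], lt$ci_low[1], lt$ci_high[1],
                sum(lt$deaths), sum(lt$person_years)))
  }
  for (s in names(x$failed)) cat(sprintf("  %-20s FAILED: %s\n", s, x$failed[[s]]))
  invisible(x)
}

#' Summarise a stratified result at a reference band
#'
#' One row per stratum: life expectancy at the given band with its standard
#' error and confidence limits, mirroring the usual published layout.
#'
#' @param x A `stratified_result`.
#' @param at_band Band index (default 1: the first band start, e.g. age 20).
#' @return A data frame with columns `stratum`, `e`, `se`, `ci_low`,
#'   `ci_high`, `deaths`, `person_years`.
#' @export
summarise_strata <- function(x, at_band = 1L) {
  stopifnot(inherits(x, "stratified_result"))
  rows <- lapply(names(x$tables), function(s) {
    lt <- x$tables[[s]]
    data.frame(
      stratum = s,
      e = lt$e[at_band], se = lt$se_e[at_band],
      ci_low = lt$ci_low[at_band], ci_high = lt$ci_high[at_band],
      deaths = sum(lt$deaths), person_years = sum(lt$person_years),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Compare life expectancy between two groups
#'
#' Two-sample z-test on two independent Chiang estimates at a reference
#' band: `diff = e1 - e2`, `SE(diff) = sqrt(SE1^2 + SE2^2)`,
#' `z = diff / SE(diff)`, two-sided p from the standard normal. The test is
#' the minimal normal-theory contrast for asymptotically normal, independent
#' estimators; it is antisymmetric in its arguments.
#'
#' @param lt1,lt2 Two `life_table`s sharing the same schema.
#' @param at_band Band index at which to compare (default 1).
#' @return A `lifetable_comparison`: list with `labels`, `e1`, `e2`, `diff`,
#'   `se`, `z`, `p_value`.
#' @export
compare_life_expectancy <- function(lt1, lt2, at_band = 1L) {
  stopifnot(inherits(lt1, "life_table"), inherits(lt2, "life_table"))
  if (!same_schema(attr(lt1, "schema"), attr(lt2, "schema"))) {
    stop("life tables use different age-band schemas")
  }
  e1 <- lt1$e[at_band]; se1 <- lt1$se_e[at_band]
  e2 <- lt2$e[at_band]; se2 <- lt2$se_e[at_band]
  diff <- e1 - e2
  se <- sqrt(se1^2 + se2^2)
  z <- if (se > 0) diff / se else 0
  p <- if (se > 0) 2 * stats::pnorm(-abs(z)) else as.numeric(diff == 0)
  structure(
    list(
      labels = c(attr(lt1, "group_label") %||% "group1",
                 attr(lt2, "group_label") %||% "group2"),
      at_age = lt1$x[at_band],
      e1 = e1, e2 = e2, diff = diff, se = se, z = z, p_value = p
    ),
    class = "lifetable_comparison"
  )
}

#' Summary z-test from published point estimates and confidence limits
#'
#' Reconstructs standard errors from reported 95% limits (`SE = width /
#' (2 * 1.96)`) and applies the same two-sample z-test as
#' [compare_life_expectancy()]. Useful for checking the internal consistency
#' of published stratified tables.
#'
#' @param e1,lo1,hi1 First group's estimate and 95% limits (years).
#' @param e2,lo2,hi2 Second group's estimate and 95% limits.
#' @return A list with `diff`, `se`, `z`, `p_value`.
#' @export
compare_from_summaries <- function(e1, lo1, hi1, e2, lo2, hi2) {
  se1 <- (hi1 - lo1) / (2 * 1.96)
  se2 <- (hi2 - lo2) / (2 * 1.96)
  if (se1 < 0 || se2 < 0) stop("confidence limits out of order")
  diff <- e1 - e2
  se <- sqrt(se1^2 + se2^2)
  z <- diff / se
  list(diff = diff, se = se, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.lifetable_comparison <- function(x, ...) {
  cat(sprintf("e(%g): %.2f vs %.2f  (%s vs %s)\n", x$at_age, x$e1, x$e2,
              x$labels[1], x$labels[2]))
  cat(sprintf("  diff = %.2f years, SE = %.3f, z = %.2f, p = %s\n",
              x$diff, x$se, x$z, format.pval(x$p_value, digits = 3, eps = 1e-300)))
  invisible(x)
}

#' Life tables by calendar period of diagnosis
#'
#' Assigns each record to the period containing its diagnosis year and
#' builds one life table per period. Periods are defined by ordered break
#' years: `period_breaks = c(1986, 2001, 2011, 2017)` gives periods
#' 1986-2000, 2001-2010, 2011-2016 (each period spans `[break_k,
#' break_{k+1})` in diagnosis year). Empty or failing periods are reported
#' as failed strata.
#'
#' @param cohort A [cohort()] of eligible, complete records.
#' @param period_breaks Increasing integer years; at least two.
#' @param schema An [age_band_schema()].
#' @param ... Passed to [stratified_life_tables()].
#' @return A `stratified_result` keyed by period label.
#' @export
period_trend <- function(cohort, period_breaks, schema = age_band_schema(), ...) {
  stopifnot(inherits(cohort, "cohort"))
  period_breaks <- as.numeric(period_breaks)
  if (length(period_breaks) < 2L || any(diff(period_breaks) <= 0)) {
    stop("period_breaks must be at least two increasing years")
  }
  yr <- as.numeric(format(cohort$records$date_of_diagnosis, "%Y"))
  labels <- sprintf("%d-%d", period_breaks[-length(period_breaks)],
                    period_breaks[-1] - 1)
  idx <- findInterval(yr, period_breaks)
  period <- rep(NA_character_, length(yr))
  inside <- idx >= 1L & idx < length(period_breaks)
  period[inside] <- labels[idx[inside]]
  if (anyNA(period)) {
    stop(sum(is.na(period)), " record(s) have diagnosis years outside the periods")
  }
  tmp <- cohort
  tmp$records$.period <- period
  out <- stratified_life_tables(tmp, ".period", schema = schema, ...)
  out$by <- "diagnosis period"
  # keep period ordering, not alphabetical
  ord <- labels[labels %in% names(out$tables)]
  out$tables <- out$tables[ord]
  out
}

#' Reference remaining life expectancy, Iran 2015 general population
#'
#' Published national remaining life expectancies at the default band starts
#' (20-24 through 65+), used as the default reference for
#' [years_of_life_lost()].
#'
#' @return Named numeric vector, one value per default band.
#' @export
iran_reference_2015 <- function() {
  e <- c(56.1, 51.5, 46.8, 42.1, 37.3, 32.6, 28.0, 23.6, 19.3, 15.2)
  names(e) <- band_labels(age_band_schema())
  e
}

#' Years of life lost
#'
#' Sums, over all deaths in the cohort, a reference remaining life
#' expectancy evaluated at the band containing the age at death: each death
#' at an age in band `j` contributes `reference_e[j]` years. No discounting
#' or age weighting is applied.
#'
#' @param cohort A [cohort()] of eligible, complete records.
#' @param reference_e Numeric vector of remaining life expectancy per band
#'   (default [iran_reference_2015()]).
#' @param schema An [age_band_schema()] with as many bands as `reference_e`.
#' @return Total years of life lost (scalar).
#' @export
years_of_life_lost <- function(cohort, reference_e = iran_reference_2015(),
                               schema = age_band_schema()) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(reference_e) != nrow(schema)) {
    stop("reference_e must supply one value per band of the schema")
  }
  r <- cohort$records[cohort$records$status == "died", , drop = FALSE]
  if (nrow(r) == 0L) return(0)
  age_death <- r$age_at_diagnosis + years_between(r$date_of_diagnosis, r$exit_date)
  j <- band_index(age_death, schema)
  if (anyNA(j)) stop("death at an age below the reference table's first band")
  sum(reference_e[j])
}

#' Ecological (group-level) correlation
#'
#' Pearson product-moment correlation between group-level life expectancies
#' and a group-level covariate (e.g. per-province life expectancy against a
#' wealth or education index). This is a correlation of aggregates, not of
#' individuals.
#'
#' @param group_e Numeric vector of per-group life expectancies (>= 3 groups).
#' @param covariate Numeric vector of the same length; must not be constant.
#' @return Pearson r.
#' @export
ecological_correlation <- function(group_e, covariate) {
  if (length(group_e) != length(covariate)) stop("vectors must have equal length")
  ok <- stats::complete.cases(group_e, covariate)
  if (sum(ok) < 3L) stop("at least 3 paired groups required")
  if (stats::sd(covariate[ok]) == 0) stop("covariate is constant; correlation undefined")
  if (stats::sd(group_e[ok]) == 0) stop("life expectancies are constant; correlation undefined")
  stats::cor(group_e[ok], covariate[ok])
}
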