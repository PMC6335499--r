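# End-to-end pipeline: load -> impute -> filter -> exposure -> life table
# -> stratified tables / period trend, with auditable file outputs.

#' Build or read a pipeline run configuration
#'
#' A run configuration names the cohort file and drives every stage of the
#' analysis. It can be given as an R list or as a YAML file with the same
#' field names. Recognised fields (all but `cohort` optional):
#' \describe{
#'   \item{cohort}{Path to the cohort CSV.}
#'   \item{column_mapping}{Named list mapping canonical column names to the
#'     file's headers.}
#'   \item{schema}{List with `starts` and optional `a` for
#'     [age_band_schema()].}
#'   \item{terminal_e_fixed}{Optional fixed terminal life expectancy.}
#'   \item{min_age}{Eligibility age floor (default 20).}
#'   \item{impute_seed}{Seed for [impute_missing()] (default 1).}
#'   \item{max_missing_fraction}{Imputation applicability threshold
#'     (default 0.10).}
#'   \item{radix}{Life-table radix (default 100000).}
#'   \item{stratify_by}{Character vector of covariates to stratify by.}
#'   \item{period_breaks}{Increasing diagnosis years for [period_trend()].}
#'   \item{study_end}{Administrative end of study (ISO date).}
#'   \item{output_dir}{Where [run_pipeline()] writes its bundle.}
#' }
#'
#' @param x A named list, or the path to a YAML file.
#' @return A validated `run_config`.
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  if (!is.list(x)) stop("config must be a list or a YAML file path")
  if (is.null(x$cohort)) stop("config field 'cohort' (file path) is required")
  defaults <- list(
    column_mapping = NULL,
    schema = NULL,
    terminal_e_fixed = NULL,
    min_age = 20,
    impute_seed = 1L,
    max_missing_fraction = 0.10,
    radix = 1e5,
    stratify_by = character(),
    period_breaks = NULL,
    study_end = NULL,
    output_dir = "cohortlife-output"
  )
  cfg <- utils::modifyList(defaults, x[!vapply(x, is.null, logical(1))])
  cfg$schema_obj <- if (is.null(cfg$schema)) age_band_schema()
                    else age_band_schema(starts = cfg$schema$starts,
                                         a = cfg$schema$a %||% 0.5)
  if (!is.null(cfg$period_breaks)) cfg$period_breaks <- as.numeric(cfg$period_breaks)
  class(cfg) <- "run_config"
  cfg
}

#' Run the whole life-expectancy pipeline
#'
#' Executes load, imputation, eligibility filtering, exposure aggregation,
#' the pooled Chiang life table, and any configured stratifications and
#' period trend; writes the output bundle to `config$output_dir`:
#' per-stratum life-table CSVs, a summary CSV (stratum, e, SE, CI), the
#' exclusion report as JSON, the resolved configuration as YAML, and a
#' plain-text report with cohort descriptives (counts, person-years, median
#' follow-up, crude mortality rate). Identical input, configuration and
#' seed give byte-identical outputs.
#'
#' @param config A [run_config()] (or list / YAML path coercible to one).
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the cohort, exclusion report, pooled
#'   exposure and life table, stratified results, and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  schema <- config$schema_obj

  say("[load] %s", config$cohort)
  coh <- load_cohort(config$cohort, mapping = config$column_mapping,
                     study_end = config$study_end)
  say("[load] %d records in", nrow(coh$records))

  coh <- impute_missing(coh, seed = config$impute_seed,
                        max_missing_fraction = config$max_missing_fraction)
  say("[impute] %s", utils::tail(coh$provenance, 1))

  flt <- filter_eligible(coh, min_age = config$min_age)
  coh <- flt$cohort
  say("[filter] %d retained, %d excluded", flt$report$n_retained,
      nrow(flt$report$excluded))

  exposure <- aggregate_exposure(coh, schema, group_label = "overall")
  lt <- build_life_table(exposure, radix = config$radix,
                         terminal_e_fixed = config$terminal_e_fixed)
  say("[lifetable] e(%g) = %.1f (95%% CI, %.1f to %.1f)",
      lt$x[1], lt$e[1], lt$ci_low[1], lt$ci_high[1])

  strata <- list()
  for (by in config$stratify_by) {
    say("[stratify] by %s", by)
    strata[[by]] <- stratified_life_tables(
      coh, by, schema, radix = config$radix,
      terminal_e_fixed = config$terminal_e_fixed
    )
  }
  trend <- NULL
  if (!is.null(config$period_breaks)) {
    say("[trend] periods %s", paste(config$period_breaks, collapse = ", "))
    trend <- period_trend(coh, config$period_breaks, schema,
                          radix = config$radix,
                          terminal_e_fixed = config$terminal_e_fixed)
  }

  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    lifetable = file.path(out_dir, "lifetable_overall.csv"),
    summary = file.path(out_dir, "summary.csv"),
    exclusions = file.path(out_dir, "exclusions.json"),
    report = file.path(out_dir, "report.txt"),
    config = file.path(out_dir, "config_resolved.yaml")
  )
  write_life_table(lt, paths[["lifetable"]])
  write_exclusion_report(flt$report, paths[["exclusions"]])

  summary_rows <- data.frame(
    variable = "overall", stratum = "overall",
    e = lt$e[1], se = lt$se_e[1], ci_low = lt$ci_low[1], ci_high = lt$ci_high[1],
    deaths = sum(lt$deaths), person_years = sum(lt$person_years),
    stringsAsFactors = FALSE
  )
  all_strat <- c(strata, if (!is.null(trend)) list(period = trend))
  for (by in names(all_strat)) {
    res <- all_strat[[by]]
    for (s in names(res$tables)) {
      slug <- gsub("[^A-Za-z0-9]+", "_", paste(by, s, sep = "_"))
      write_life_table(res$tables[[s]],
                       file.path(out_dir, sprintf("lifetable_%s.csv", slug)))
    }
    sm <- summarise_strata(res)
    summary_rows <- rbind(summary_rows, cbind(variable = by, sm))
  }
  utils::write.csv(format(summary_rows, digits = 15, trim = TRUE, scientific = FALSE),
                   paths[["summary"]], row.names = FALSE, quote = FALSE)

  writeLines(render_text_report(coh, flt$report, exposure, lt, all_strat),
             paths[["report"]])
  cfg_out <- config
  cfg_out$schema_obj <- NULL
  class(cfg_out) <- NULL
  yaml::write_yaml(cfg_out, paths[["config"]])
  say("[done] bundle in %s", out_dir)

  invisible(list(
    cohort = coh, exclusions = flt$report, exposure = exposure,
    life_table = lt, strata = strata, trend = trend, paths = paths
  ))
}

# One-decimal presentation for the text report; CSV/JSON keep full precision.
render_text_report <- function(cohort, report, exposure, lt, strata) {
  r <- cohort$records
  fup <- years_between(r$date_of_diagnosis, r$exit_date)
  lines <- c(
    "Cohort life-expectancy report",
    strrep("=", 60),
    sprintf("Records analysed:      %d (of %d loaded; %d excluded)",
            report$n_retained, report$n_input, nrow(report$excluded)),
    sprintf("Total person-years:    %.0f", sum(exposure$person_years)),
    sprintf("Median follow-up:      %.1f years", stats::median(fup)),
    sprintf("Deaths:                %d", sum(exposure$deaths)),
    sprintf("Crude mortality rate:  %.1f per 1,000 person-years",
            crude_mortality_rate(exposure)),
    "",
    sprintf("Life expectancy at age %g: %.1f years (95%% CI, %.1f to %.1f)",
            lt$x[1], lt$e[1], lt$ci_low[1], lt$ci_high[1]),
    ""
  )
  for (by in names(strata)) {
    lines <- c(lines, sprintf("By %s:", by))
    sm <- summarise_strata(strata[[by]])
    lines <- c(lines, sprintf("  %-24s %5.1f (95%% CI, %.1f to %.1f)",
                              sm$stratum, sm$e, sm$ci_low, sm$ci_high))
    for (s in names(strata[[by]]$failed)) {
      lines <- c(lines, sprintf("  %-24s failed: %s", s, strata[[by]]$failed[[s]]))
    }
    lines <- c(lines, "")
  }
  lines
}
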