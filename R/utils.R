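# Internal helpers shared across modules.

# Mean Gregorian year length; all day<->year conversions go through this so
# that calendar arithmetic is translation-invariant.
DAYS_PER_YEAR <- 365.2425

years_between <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}

#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Parse ISO-8601 dates strictly; anything else becomes NA (and is counted by
# the caller). Empty strings are missing, not errors.
parse_iso_date <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(trimws(x))] <- NA_character_
  out <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", trimws(x))
  out[ok] <- as.Date(trimws(x[ok]), format = "%Y-%m-%d")
  out
}

parse_num <- function(x) {
  suppressWarnings(as.numeric(as.character(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
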