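#' Age-band schema for abridged life tables
#'
#' Defines the ordered, contiguous age intervals over which person-time is
#' split and the life table is built. The last band is always open-ended
#' (width `Inf`). Each band carries `a`, the average fraction of the interval
#' lived by those who die within it; `a = 0.5` is the conventional
#' abridged-table assumption.
#'
#' The default schema is the one used throughout HIV-cohort life-expectancy
#' work: 5-year bands 20-24 through 60-64 plus an open 65+ band.
#'
#' @param starts Increasing numeric vector of band start ages (years). The
#'   final start opens the terminal band.
#' @param a Fraction of interval survived by decedents, recycled to one value
#'   per band; each must lie in `[0, 1]`.
#' @return A data frame of class `age_band_schema` with columns `start`,
#'   `width` (`Inf` for the terminal band), and `a`.
#' @examples
#' age_band_schema()
#' age_band_schema(starts = c(20, 30, 40, 50), a = 0.5)
#' @export
age_band_schema <- function(starts = c(seq(20, 60, by = 5), 65), a = 0.5) {
  starts <- as.numeric(starts)
  if (length(starts) < 2L) {
    stop("schema needs at least one closed band and one open terminal band")
  }
  if (any(!is.finite(starts)) || any(diff(starts) <= 0)) {
    stop("band starts must be finite and strictly increasing")
  }
  a <- rep_len(as.numeric(a), length(starts))
  if (any(!is.finite(a)) || any(a < 0) || any(a > 1)) {
    stop("'a' values must lie in [0, 1]")
  }
  out <- data.frame(
    start = starts,
    width = c(diff(starts), Inf),
    a = a
  )
  class(out) <- c("age_band_schema", "data.frame")
  out
}

#' @export
print.age_band_schema <- function(x, ...) {
  w <- nrow(x)
  lab <- band_labels(x)
  cat(sprintf("Age-band schema: %d bands (%s ... %s)\n", w, lab[1], lab[w]))
  print.data.frame(cbind(band = lab, as.data.frame(x)), row.names = FALSE)
  invisible(x)
}

band_labels <- function(schema) {
  end <- schema$start + schema$width
  # integer-width closed bands print in the conventional "20-24" style
  lab <- ifelse(schema$width >= 1 & end == round(end),
                sprintf("%g-%g", schema$start, end - 1),
                sprintf("%g-%g", schema$start, end))
  ifelse(is.finite(schema$width), lab, sprintf("%g+", schema$start))
}

#' Locate the band containing each exact age
#'
#' Bands are half-open `[start, start + width)`, so an age exactly on a
#' boundary belongs to the higher band; the terminal band is unbounded above.
#'
#' @param age Numeric vector of exact ages (years).
#' @param schema An [age_band_schema()].
#' @return Integer band indices; `NA` for ages below the first band start.
#' @export
band_index <- function(age, schema) {
  idx <- findInterval(age, schema$start)
  idx[idx == 0L] <- NA_integer_
  idx
}

same_schema <- function(s1, s2) {
  isTRUE(all.equal(s1$start, s2$start)) && isTRUE(all.equal(s1$a, s2$a))
}
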