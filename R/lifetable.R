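# Chiang abridged (bridge) life table: rate -> probability conversion,
# synthetic-cohort propagation, life expectancy, and its sampling variance.

#' Convert an age-specific mortality rate to an interval death probability
#'
#' Uses Chiang's conversion for an interval of width `n` years in which
#' decedents live on average a fraction `a` of the interval:
#' \deqn{q = \frac{n m}{1 + n (1 - a) m},}
#' clamped at 1. For the open terminal band (`n = Inf`) the probability of
#' dying is 1 by construction.
#'
#' @param m Age-specific mortality rate (deaths per person-year), `>= 0`.
#' @param n Interval width in years (`Inf` for the open band).
#' @param a Fraction of the interval survived by decedents, in `[0, 1]`.
#' @return The conditional probability of dying in the interval. Vectorised.
#' @examples
#' rate_to_probability(0.1, 5, 0.5)   # 0.4
#' rate_to_probability(10, 5, 0.5)    # clamped to 1
#' @export
rate_to_probability <- function(m, n, a = 0.5) {
  if (any(is.na(m)) || any(m < 0)) stop("mortality rate m must be >= 0")
  if (any(n <= 0)) stop("interval width n must be positive")
  if (any(a < 0 | a > 1)) stop("'a' must lie in [0, 1]")
  q <- ifelse(is.finite(n), pmin(1, n * m / (1 + n * (1 - a) * m)), 1)
  q
}

#' Build a Chiang abridged life table from band-level exposure
#'
#' Computes, per band: the mortality rate `m = D / PY`, the death probability
#' `q` via [rate_to_probability()], survivors `l` (radix-scaled), deaths `d`,
#' person-years lived `L`, person-years above the band start `T`, life
#' expectancy `e = T / l`, and the Chiang standard error of `e` with 95%
#' confidence limits (see [variance_of_life_expectancy()]).
#'
#' For closed bands, `L = n (l_next + a d)`. For the open terminal band the
#' default convention is exponential: `q = 1`, `L = l / m`, `e = 1 / m`,
#' which requires at least one terminal death; `terminal_e_fixed` instead
#' pins the terminal remaining life expectancy at a stated value (some
#' published tables fix it), in which case `L = l * e_fixed` and the terminal
#' band contributes no variance.
#'
#' @param exposure An `exposure_table` from [aggregate_exposure()].
#' @param radix Starting size of the synthetic cohort (default 100000); all
#'   rates, probabilities, `e` and `SE` are invariant to it.
#' @param terminal_e_fixed Optional fixed remaining life expectancy (years)
#'   for the open band, overriding the `1/m` convention.
#' @param level Confidence level (default 0.95, giving the conventional
#'   `e +/- 1.96 SE` limits).
#' @return A `life_table`: a data frame with one row per band and columns
#'   `band`, `x` (band start), `n`, `a`, `deaths`, `person_years`, `m`, `q`,
#'   `p`, `l`, `d`, `L`, `T`, `e`, `var_p`, `se_e`, `ci_low`, `ci_high`.
#' @export
build_life_table <- function(exposure, radix = 1e5, terminal_e_fixed = NULL,
                             level = 0.95) {
  stopifnot(inherits(exposure, "exposure_table"))
  schema <- attr(exposure, "schema")
  w <- nrow(exposure)
  D <- exposure$deaths
  PY <- exposure$person_years
  n <- exposure$band_width
  a <- exposure$a

  closed <- seq_len(w - 1L)
  if (any(PY[closed] <= 0)) {
    stop("closed band(s) with zero person-years: ",
         paste(exposure$band[closed][PY[closed] <= 0], collapse = ", "),
         "; merge bands or widen the schema")
  }

  m <- ifelse(PY > 0, D / PY, 0)
  q <- rate_to_probability(m, n, a)
  q[w] <- 1
  p <- 1 - q

  l <- numeric(w)
  l[1] <- radix
  for (j in closed) l[j + 1L] <- l[j] * p[j]
  d <- l * q

  # The 1/m terminal convention needs observed terminal deaths -- but only
  # when anyone survives into the open band at all.
  if (l[w] > 0 && is.null(terminal_e_fixed) && D[w] == 0L) {
    stop("no deaths in the open terminal band ", exposure$band[w],
         "; terminal life expectancy 1/m is undefined - extend the open band",
         " or supply terminal_e_fixed")
  }

  L <- numeric(w)
  L[closed] <- n[closed] * (l[closed + 1L] + a[closed] * d[closed])
  e_w <- if (!is.null(terminal_e_fixed)) terminal_e_fixed
         else if (l[w] > 0) 1 / m[w] else 0
  L[w] <- l[w] * e_w
  T <- rev(cumsum(rev(L)))
  e <- ifelse(l > 0, T / l, 0)

  lt <- data.frame(
    band = exposure$band,
    x = exposure$band_start,
    n = n, a = a,
    deaths = D, person_years = PY,
    m = m, q = q, p = p, l = l, d = d, L = L, T = T, e = e
  )
  attr(lt, "schema") <- schema
  attr(lt, "radix") <- radix
  attr(lt, "group_label") <- attr(exposure, "group_label")
  attr(lt, "terminal_e_fixed") <- terminal_e_fixed
  attr(lt, "level") <- level
  class(lt) <- c("life_table", "data.frame")

  se <- variance_of_life_expectancy(lt, exposure)
  lt$var_p <- attr(se, "var_p")
  lt$se_e <- as.numeric(se)
  ci <- confidence_interval(lt$e, lt$se_e, level = level)
  lt$ci_low <- ci$low
  lt$ci_high <- ci$high
  lt
}

#' Chiang standard error of life expectancy
#'
#' Implements the Chiang sampling variance of the abridged-table life
#' expectancy. The variance of the interval survival probability is
#' \deqn{S^2(p_j) = q_j^2 p_j / D_j}
#' (zero when a band has no deaths: `q = 0` is then exact), and the variance
#' of the life expectancy at the start of band `i` sums over the closed
#' bands at or above `i`:
#' \deqn{S^2(e_i) = \frac{1}{l_i^2} \sum_{j=i}^{w-1}
#'   l_j^2 \left[(1 - a_j) n_j + e_{j+1}\right]^2 S^2(p_j).}
#' The open terminal band, absent from that sum, is handled by a delta-method
#' extension: with `e_w = 1/m_w` and the terminal death count treated as
#' Poisson, `Var(e_w) = 1 / (m_w^2 D_w)`, propagated as
#' `(l_w / l_i)^2 Var(e_w)`. Without this term the standard error near the
#' open band would be understated. When the terminal expectancy is pinned by
#' `terminal_e_fixed`, the terminal term is zero.
#'
#' @param lifetable A `life_table` from [build_life_table()].
#' @param exposure The `exposure_table` the table was built from (supplies
#'   the death counts `D_j`).
#' @return Numeric vector of `SE(e)` per band, with the per-band `S^2(p)` in
#'   attribute `var_p`.
#' @export
variance_of_life_expectancy <- function(lifetable, exposure) {
  stopifnot(inherits(lifetable, "life_table"), inherits(exposure, "exposure_table"))
  w <- nrow(lifetable)
  D <- exposure$deaths
  q <- lifetable$q
  p <- lifetable$p
  l <- lifetable$l
  e <- lifetable$e
  n <- lifetable$n
  a <- lifetable$a

  var_p <- ifelse(D > 0, q^2 * p / D, 0)
  var_p[w] <- 0  # terminal band handled separately

  var_ew <- 0
  if (is.null(attr(lifetable, "terminal_e_fixed")) && D[w] > 0) {
    m_w <- lifetable$m[w]
    var_ew <- 1 / (m_w^2 * D[w])
  }

  # per-band summand of the Chiang sum (closed bands only)
  summand <- numeric(w)
  if (w > 1L) {
    j <- seq_len(w - 1L)
    summand[j] <- l[j]^2 * ((1 - a[j]) * n[j] + e[j + 1L])^2 * var_p[j]
  }
  se <- numeric(w)
  for (i in seq_len(w)) {
    if (l[i] <= 0) { se[i] <- 0; next }
    tail_sum <- if (i <= w - 1L) sum(summand[i:(w - 1L)]) else 0
    se[i] <- sqrt(tail_sum / l[i]^2 + (l[w] / l[i])^2 * var_ew)
  }
  attr(se, "var_p") <- var_p
  se
}

#' Normal-theory confidence interval for life expectancy
#'
#' Lower and upper limits `e -/+ z SE`. At the conventional 95% level the
#' multiplier is exactly 1.96; other levels use the corresponding standard
#' normal quantile.
#'
#' @param e Life expectancy (years).
#' @param se Standard error (years), `>= 0`.
#' @param level Confidence level in (0, 1).
#' @return A list with numeric `low` and `high`. Vectorised.
#' @export
confidence_interval <- function(e, se, level = 0.95) {
  if (any(is.na(se)) || any(se < 0)) stop("standard error must be >= 0")
  z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  list(low = e - z * se, high = e + z * se)
}

#' @export
print.life_table <- function(x, digits = 2, ...) {
  lbl <- attr(x, "group_label")
  cat(sprintf("Chiang abridged life table%s (radix %g)\n",
              if (is.null(lbl)) "" else paste0(" [", lbl, "]"),
              attr(x, "radix")))
  cat(sprintf("  e(%g) = %.1f years (95%% CI, %.1f to %.1f)\n",
              x$x[1], x$e[1], x$ci_low[1], x$ci_high[1]))
  df <- as.data.frame(x)[, c("band", "deaths", "person_years", "m", "q",
                             "l", "L", "T", "e", "se_e", "ci_low", "ci_high")]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, digits + 2))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Write a life table to CSV at full precision
#'
#' @param lifetable A `life_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lifetable, path) {
  utils::write.csv(as.data.frame(lifetable), path, row.names = FALSE)
  invisible(path)
}
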