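# Age-banded demographic containers and arithmetic.
#
# Age bands are stored with inclusive printed-style endpoints (age_lo, age_hi)
# and converted internally to half-open intervals [age_lo, age_hi + 1); an
# open-ended top band is written age_hi = Inf. Rates are assumed uniform
# within a band, so band intersection apportions counts linearly in overlap
# width.

#' Age-banded population table
#'
#' A population for one region and calendar year, broken into ordered,
#' non-overlapping age bands, optionally by sex.
#'
#' @param region character label.
#' @param year integer calendar year.
#' @param bands data frame with columns `age_lo` (years, inclusive),
#'   `age_hi` (years, inclusive; `Inf` marks an open-ended top band),
#'   `sex` (`"all"`, `"female"` or `"male"`; optional, default `"all"`)
#'   and `count` (persons, non-negative).
#' @return An object of class `age_band_population`.
#' @examples
#' age_band_population("Canada", 2020,
#'   data.frame(age_lo = c(60, 65), age_hi = c(64, Inf),
#'              count = c(2.4e6, 6.5e6)))
#' @export
age_band_population <- function(region, year, bands) {
  bands <- as.data.frame(bands)
  if (is.null(bands$sex)) bands$sex <- "all"
  required <- c("age_lo", "age_hi", "sex", "count")
  if (!all(required %in% names(bands))) {
    stop("`bands` needs columns age_lo, age_hi, count (and optionally sex)",
         call. = FALSE)
  }
  bands <- bands[, required]
  if (any(bands$count < 0)) stop("band counts must be non-negative", call. = FALSE)
  if (any(bands$age_hi < bands$age_lo)) {
    stop("age_hi must be >= age_lo in every band", call. = FALSE)
  }
  for (s in unique(bands$sex)) {
    b <- bands[bands$sex == s, ]
    b <- b[order(b$age_lo), ]
    if (sum(is.infinite(b$age_hi)) > 1L) {
      stop("at most one open-ended top band per sex", call. = FALSE)
    }
    if (nrow(b) > 1L && any(b$age_hi[-nrow(b)] + 1 > b$age_lo[-1L])) {
      stop("age bands must be non-overlapping and ascending", call. = FALSE)
    }
  }
  structure(
    list(region = as.character(region), year = as.integer(year),
         bands = bands[order(bands$sex, bands$age_lo), , drop = FALSE]),
    class = "age_band_population"
  )
}

#' @export
print.age_band_population <- function(x, ...) {
  cat(sprintf("<age_band_population> %s, %d — %d band(s), %s persons\n",
              x$region, x$year, nrow(x$bands),
              format(sum(x$bands$count), big.mark = ",")))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Age-specific rate schedule
#'
#' Banded rates driving all demographic arithmetic: either prevalence
#' proportions (dimensionless, in `[0, 1]`) or incidence rates per 1,000
#' person-years.
#'
#' @param kind `"prevalence_proportion"` or `"incidence_per_1000py"`.
#' @param entries data frame with columns `age_lo`, `age_hi` (inclusive,
#'   `Inf` allowed), optional `sex`, and `rate` (non-negative; proportions
#'   additionally at most 1).
#' @return An object of class `rate_schedule`.
#' @examples
#' rate_schedule("incidence_per_1000py",
#'   data.frame(age_lo = 60, age_hi = 64, rate = 3.9))
#' @export
rate_schedule <- function(kind = c("prevalence_proportion", "incidence_per_1000py"),
                          entries) {
  kind <- match.arg(kind)
  entries <- as.data.frame(entries)
  if (is.null(entries$sex)) entries$sex <- "all"
  required <- c("age_lo", "age_hi", "sex", "rate")
  if (!all(required %in% names(entries))) {
    stop("`entries` needs columns age_lo, age_hi, rate (and optionally sex)",
         call. = FALSE)
  }
  entries <- entries[, required]
  if (any(entries$rate < 0)) stop("rates must be non-negative", call. = FALSE)
  if (kind == "prevalence_proportion" && any(entries$rate > 1)) {
    stop("prevalence proportions must be <= 1", call. = FALSE)
  }
  structure(
    list(kind = kind,
         entries = entries[order(entries$sex, entries$age_lo), , drop = FALSE]),
    class = "rate_schedule"
  )
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat(sprintf("<rate_schedule> %s — %d entries\n", x$kind, nrow(x$entries)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Rate applying at given ages
#'
#' Looks up the banded rate covering each age (bands are inclusive of both
#' printed endpoints); entries for sex `"all"` back any requested sex.
#'
#' @param schedule a [rate_schedule()].
#' @param age ages (years).
#' @param sex sex label(s), recycled.
#' @return Rates, `NA` where no band covers an age.
#' @examples
#' sch <- doubling_schedule()
#' rate_at(sch, c(62, 90))
#' @export
rate_at <- function(schedule, age, sex = "all") {
  e <- schedule$entries
  vapply(seq_along(age), function(i) {
    ok <- (e$sex == sex[[min(i, length(sex))]] | e$sex == "all") &
      e$age_lo <= age[[i]] & age[[i]] < e$age_hi + 1
    if (!any(ok)) return(NA_real_)
    e$rate[which(ok)[1L]]
  }, numeric(1))
}

#' Counts of prevalent or incident cases by age band
#'
#' @param region character label.
#' @param quantity `"prevalence"` or `"incidence"`.
#' @param values data frame with columns `year`, `age_lo`, `age_hi`, `sex`,
#'   `count` (non-negative).
#' @return An object of class `count_table`.
#' @export
count_table <- function(region, quantity = c("prevalence", "incidence"), values) {
  quantity <- match.arg(quantity)
  values <- as.data.frame(values)
  if (is.null(values$sex)) values$sex <- "all"
  required <- c("year", "age_lo", "age_hi", "sex", "count")
  if (!all(required %in% names(values))) {
    stop("`values` needs columns year, age_lo, age_hi, count", call. = FALSE)
  }
  if (any(values$count < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(region = as.character(region), quantity = quantity,
                 values = values[, required]),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %s %s — total %s\n", x$region, x$quantity,
              format(sum(x$values$count), big.mark = ",")))
  print(x$values, row.names = FALSE)
  invisible(x)
}

#' Total count over an age range
#'
#' Sums a [count_table()] over `[age_lo, age_hi]`, apportioning bands that
#' straddle a boundary linearly in overlap width (rates and hence counts are
#' taken uniform within a band).
#'
#' @param ct a [count_table()].
#' @param age_lo,age_hi inclusive age range; `age_hi = Inf` for an open range.
#' @param sex restrict to one sex label, or `NULL` (default) for all rows.
#' @return Total persons in range.
#' @export
count_in_range <- function(ct, age_lo, age_hi = Inf, sex = NULL) {
  v <- ct$values
  if (!is.null(sex)) v <- v[v$sex == sex, , drop = FALSE]
  lo <- v$age_lo; hi <- v$age_hi + 1      # half-open
  qlo <- age_lo; qhi <- if (is.infinite(age_hi)) Inf else age_hi + 1
  width <- hi - lo
  overlap <- pmax(0, pmin(hi, qhi) - pmax(lo, qlo))
  frac <- ifelse(width > 0 & is.finite(width), overlap / width,
                 as.numeric(overlap > 0))   # open-ended band: all or nothing
  sum(v$count * frac)
}

#' Population growth factor and percent increase
#'
#' `growth_factor()` returns the ratio `end / start`;
#' `percent_increase()` returns `(end / start - 1) * 100` rounded half-up to
#' one decimal, the form used in printed demographic tables.
#'
#' @param start population at the start of the period (> 0).
#' @param end population at the end of the period (>= 0).
#' @return Dimensionless ratio, or percent for `percent_increase()`.
#' @examples
#' growth_factor(769413, 1406105)    # 1.8275...
#' percent_increase(769413, 1406105) # 82.8
#' @export
growth_factor <- function(start, end) {
  stop_if_not_number(start, "start", lower = 0, strict_lower = TRUE)
  stop_if_not_number(end, "end", lower = 0)
  end / start
}

#' @rdname growth_factor
#' @export
percent_increase <- function(start, end) {
  round_half_up((growth_factor(start, end) - 1) * 100, 1)
}

#' Apply a rate schedule to an age-banded population
#'
#' Expected case counts per band: `count * proportion` for prevalence
#' schedules, `count * rate / 1000` for incidence rates per 1,000
#' person-years over a one-year horizon. A population band split across
#' several rate bands is apportioned linearly in overlap width.
#'
#' @param pop an [age_band_population()].
#' @param rates a [rate_schedule()] covering every population band (a gap
#'   raises an error naming the uncovered interval).
#' @return A [count_table()] with one row per population band.
#' @examples
#' pop <- age_band_population("toy", 2020,
#'   data.frame(age_lo = 60, age_hi = 64, count = 1e6))
#' sch <- rate_schedule("incidence_per_1000py",
#'   data.frame(age_lo = 60, age_hi = 64, rate = 3.9))
#' count_in_range(apply_rates(pop, sch), 60) # 3900
#' @export
apply_rates <- function(pop, rates) {
  stopifnot(inherits(pop, "age_band_population"), inherits(rates, "rate_schedule"))
  conv <- if (rates$kind == "incidence_per_1000py") 1 / 1000 else 1
  out <- pop$bands
  out$count <- vapply(seq_len(nrow(out)), function(i) {
    band_expected_cases(out$age_lo[i], out$age_hi[i], out$sex[i],
                        out$count[i], rates) * conv
  }, numeric(1))
  count_table(pop$region,
              if (rates$kind == "incidence_per_1000py") "incidence" else "prevalence",
              cbind(year = pop$year, out))
}

# count * rate summed over the rate bands intersecting one population band
# (before the per-1000 conversion). Errors on coverage gaps.
band_expected_cases <- function(age_lo, age_hi, sex, count, rates) {
  e <- rates$entries
  e <- e[e$sex == sex | e$sex == "all", , drop = FALSE]
  lo <- age_lo; hi <- age_hi + 1
  if (is.infinite(hi)) {
    ok <- e$age_lo <= lo & is.infinite(e$age_hi)
    if (!any(ok)) {
      stop(sprintf("rate schedule does not cover open-ended band %g+ (%s)",
                   age_lo, sex), call. = FALSE)
    }
    return(count * e$rate[which(ok)[1L]])
  }
  r_lo <- e$age_lo; r_hi <- e$age_hi + 1
  overlap <- pmax(0, pmin(hi, r_hi) - pmax(lo, r_lo))
  if (sum(overlap) < (hi - lo) - 1e-9) {
    covered <- sum(overlap)
    stop(sprintf(
      "rate schedule covers only %.3g of %.3g years of band %g-%g (%s)",
      covered, hi - lo, age_lo, age_hi, sex), call. = FALSE)
  }
  sum(count * (overlap / (hi - lo)) * e$rate)
}

#' Incident cases from the at-risk population
#'
#' The standard incidence-estimation procedure for dementia projections:
#' the number at risk in each age band is the total population minus the
#' prevalent cases, and incident cases are the at-risk count times the
#' age-specific incidence rate.
#'
#' @param pop an [age_band_population()].
#' @param prevalent a [count_table()] of prevalent cases whose rows align
#'   with `pop`'s bands (same `age_lo`, `age_hi`, `sex`).
#' @param inc_rates an incidence [rate_schedule()] (per 1,000 person-years).
#' @return A [count_table()] of incident cases per band.
#' @examples
#' pop <- age_band_population("toy", 2020,
#'   data.frame(age_lo = 60, age_hi = 64, count = 1e5))
#' prev <- count_table("toy", "prevalence",
#'   data.frame(year = 2020, age_lo = 60, age_hi = 64, count = 1e4))
#' sch <- rate_schedule("incidence_per_1000py",
#'   data.frame(age_lo = 60, age_hi = 64, rate = 10))
#' count_in_range(adi_incidence(pop, prev, sch), 60) # (1e5 - 1e4) * 0.01 = 900
#' @export
adi_incidence <- function(pop, prevalent, inc_rates) {
  stopifnot(inherits(pop, "age_band_population"),
            inherits(prevalent, "count_table"),
            inherits(inc_rates, "rate_schedule"),
            inc_rates$kind == "incidence_per_1000py")
  b <- pop$bands
  pv <- prevalent$values
  key <- function(d) paste(d$age_lo, d$age_hi, d$sex)
  idx <- match(key(b), key(pv))
  if (anyNA(idx)) {
    stop("prevalent counts must align with the population's age bands",
         call. = FALSE)
  }
  prev_counts <- pv$count[idx]
  if (any(prev_counts > b$count + 1e-9)) {
    stop("prevalent cases exceed the population in at least one band",
         call. = FALSE)
  }
  at_risk <- pop
  at_risk$bands$count <- pmax(b$count - prev_counts, 0)
  out <- apply_rates(at_risk, inc_rates)
  out$quantity <- "incidence"
  out
}

#' Incidence as a percentage of prevalence
#'
#' @param incidence annual incident cases.
#' @param prevalence prevalent cases (> 0).
#' @return `100 * incidence / prevalence`, rounded half-up to one decimal.
#' @examples
#' incidence_prevalence_ratio(131000, 639000) # 20.5
#' @export
incidence_prevalence_ratio <- function(incidence, prevalence) {
  stop_if_not_number(incidence, "incidence", lower = 0)
  stop_if_not_number(prevalence, "prevalence", lower = 0, strict_lower = TRUE)
  round_half_up(100 * incidence / prevalence, 1)
}

#' Exponential age-doubling incidence
#'
#' Dementia incidence approximately doubles with every fixed increment of
#' age. `doubling_rate()` is the closed form
#' `base_rate * 2^((age - anchor_age) / doubling_years)`;
#' `doubling_schedule()` tabulates it at band midpoints into a
#' [rate_schedule()].
#'
#' The printed anchor rates at the extremes of published tables are not
#' exactly consistent with a single doubling time, so this is a generator of
#' plausible schedules through one anchor, not a reproduction of any
#' particular table.
#'
#' @param age ages (years) at which to evaluate the rate.
#' @param base_rate rate per 1,000 person-years at `anchor_age` (> 0).
#' @param anchor_age age anchoring the curve.
#' @param doubling_years years of age per doubling (> 0).
#' @return `doubling_rate()`: rates per 1,000 person-years;
#'   `doubling_schedule()`: a [rate_schedule()].
#' @examples
#' doubling_rate(68.3, base_rate = 3.9, anchor_age = 62) # 7.8
#' @export
doubling_rate <- function(age, base_rate = 3.9, anchor_age = 62,
                          doubling_years = 6.3) {
  stop_if_not_number(base_rate, "base_rate", lower = 0, strict_lower = TRUE)
  stop_if_not_number(doubling_years, "doubling_years", lower = 0,
                     strict_lower = TRUE)
  base_rate * 2^((age - anchor_age) / doubling_years)
}

#' @rdname doubling_rate
#' @param age_lo,age_hi inclusive age range to tabulate.
#' @param band_width band width in years.
#' @param open_top if `TRUE`, the last band is open-ended (rate at its lower
#'   midpoint-equivalent `age_lo + (band_width - 1) / 2`).
#' @export
doubling_schedule <- function(base_rate = 3.9, anchor_age = 62,
                              doubling_years = 6.3, age_lo = 60, age_hi = 94,
                              band_width = 5, open_top = TRUE) {
  los <- seq(age_lo, age_hi, by = band_width)
  his <- pmin(los + band_width - 1, age_hi)
  if (open_top) his[length(his)] <- Inf
  mids <- los + (band_width - 1) / 2
  rate_schedule("incidence_per_1000py",
                data.frame(age_lo = los, age_hi = his,
                           rate = doubling_rate(mids, base_rate, anchor_age,
                                                doubling_years)))
}
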