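# Plain-text (CSV) serialisation of the demographic containers. Numbers are
# written with 17 significant digits so a write/read round trip is exact;
# an open-ended top band is written with the sentinel "inf".

fmt_num <- function(x) {
  ifelse(is.infinite(x), "inf", sprintf("%.17g", x))
}

parse_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[tolower(trimws(x)) == "inf"] <- Inf
  out
}

#' Read and write rate schedules as CSV
#'
#' Columns `age_lo`, `age_hi`, `sex`, `rate`; `age_hi` uses the sentinel
#' `"inf"` for an open-ended top band. The round trip is exact.
#'
#' @param schedule a [rate_schedule()].
#' @param path file path.
#' @param kind schedule kind for [read_rate_schedule()].
#' @return `read_rate_schedule()` returns a [rate_schedule()];
#'   `write_rate_schedule()` returns `path` invisibly.
#' @export
write_rate_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "rate_schedule"))
  e <- schedule$entries
  out <- data.frame(age_lo = fmt_num(e$age_lo), age_hi = fmt_num(e$age_hi),
                    sex = e$sex, rate = fmt_num(e$rate))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_schedule
#' @export
read_rate_schedule <- function(path, kind = c("prevalence_proportion",
                                              "incidence_per_1000py")) {
  kind <- match.arg(kind)
  d <- read.csv(path, colClasses = "character")
  rate_schedule(kind, data.frame(age_lo = parse_num(d$age_lo),
                                 age_hi = parse_num(d$age_hi),
                                 sex = d$sex, rate = parse_num(d$rate)))
}

#' Read and write age-banded populations as CSV
#'
#' Columns `region`, `year`, `age_lo`, `age_hi`, `sex`, `count`; `age_hi`
#' uses the sentinel `"inf"` for an open-ended top band.
#'
#' @param pop an [age_band_population()].
#' @param path file path.
#' @return `read_population()` returns an [age_band_population()];
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(inherits(pop, "age_band_population"))
  b <- pop$bands
  out <- data.frame(region = pop$region, year = pop$year,
                    age_lo = fmt_num(b$age_lo), age_hi = fmt_num(b$age_hi),
                    sex = b$sex, count = fmt_num(b$count))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  d <- read.csv(path, colClasses = "character")
  age_band_population(d$region[1], as.integer(d$year[1]),
                      data.frame(age_lo = parse_num(d$age_lo),
                                 age_hi = parse_num(d$age_hi),
                                 sex = d$sex, count = parse_num(d$count)))
}

#' Write a cohort trajectory as CSV
#'
#' Long format: `year`, `age`, `sex`, `non_demented`, `demented`, `in_care`.
#'
#' @param traj a `cohort_trajectory` from [project_cohort()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged demographic tables
#'
#' Loads one of the plain-text tables shipped with the package:
#' * `"table1_population"` — population (thousands) by region for 2010 and
#'   2030, age groups all/60+/80+, with the published 2030/2010 ratios;
#' * `"table2_prevalence"` — dementia prevalence (thousands) by region,
#'   2010–2050;
#' * `"table3_incidence"` — annual dementia incidence (thousands) by region
#'   and age group (60–79, 60+), 2010/2020/2030.
#'
#' Counts are in thousands of persons, as printed in the source tables.
#'
#' @param name table name.
#' @return A data frame.
#' @examples
#' head(load_fixture("table2_prevalence"))
#' @export
load_fixture <- function(name = c("table1_population", "table2_prevalence",
                                  "table3_incidence")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "demscreen")
  if (path == "") stop(sprintf("packaged table `%s` not found", name),
                       call. = FALSE)
  read.csv(path, stringsAsFactors = FALSE)
}
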