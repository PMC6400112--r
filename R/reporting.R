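# End-to-end reproduction of the headline quantities of the reference
# analysis, each recomputed from the packaged inputs and compared against
# its expected value.

#' Default run configuration
#'
#' Named blocks of model parameters (see [default_parameters()] for units
#' and meaning). `run_config()` merges user overrides into the defaults and
#' rejects unknown block or parameter names.
#'
#' @param ... named blocks (`economic`, `test`, `cost`, `demand`,
#'   `radiation`, `business`, `delay`, `demographic`), each a named list of
#'   overrides.
#' @return A validated configuration list of class `run_config`.
#' @examples
#' run_config(test = list(se = 0.95))
#' @export
run_config <- function(...) {
  defaults <- default_parameters()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown configuration block(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (block in names(overrides)) {
    bad <- setdiff(names(overrides[[block]]), names(defaults[[block]]))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in block `%s`: %s", block,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    defaults[[block]][names(overrides[[block]])] <- overrides[[block]]
  }
  structure(defaults, class = "run_config")
}

config_test <- function(cfg) {
  test_characteristics(cfg$test$se, cfg$test$sp, cfg$test$p)
}

config_economic <- function(cfg) {
  e <- cfg$economic
  economic_params(wtp_base = e$wtp_base, inflation_factor = e$inflation_factor,
                  fx_rate = e$fx_rate, qaly_weight = e$qaly_weight,
                  delay_years = e$delay_years,
                  annual_care_savings = e$annual_care_savings,
                  therapy_cost_annual = e$therapy_cost_annual,
                  scan_cost = e$scan_cost, discount_rate = e$discount_rate,
                  fn_penalty = e$fn_penalty)
}

#' Recompute every headline result of the reference analysis
#'
#' Runs the full pipeline at the configuration's parameters: the QALY
#' valuation, utility matrix and expected value; the per-scan cost
#' build-up and buffer infrastructure value; the screening-demand /
#' scanner-fleet table for Canada, the USA and China from the packaged
#' incidence table; the radiation-risk pair; net savings per detected
#' case; the manufacturer's revenue model; and the demographic growth and
#' incidence/prevalence ratios from the packaged tables. Each quantity is
#' compared with its expected headline value.
#'
#' @param config a [run_config()].
#' @return Data frame of class `headline_report` with columns `check`,
#'   `expected`, `computed`, `comparator` and `pass`.
#' @examples
#' rep <- reproduce_headline_results()
#' all(rep$pass)
#' @export
reproduce_headline_results <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- config_economic(config)
  test <- config_test(config)
  u <- build_utility_matrix(params)

  checks <- list()
  add <- function(check, expected, computed, comparator = "==") {
    pass <- switch(comparator,
                   "==" = isTRUE(all.equal(expected, computed, tolerance = 1e-9)),
                   "<=" = computed <= expected,
                   stop("unknown comparator"))
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      comparator = comparator, pass = pass)
  }

  add("annual QALY value (CAD, 1 decimal)",
      39811.2, round_half_up(qaly_annual_value(params), 1))
  add("utility of a true positive (CAD)", 308056, u$u_tp)
  add("utility of a false positive (CAD)", -26000, u$u_fp)
  add("expected value per screened subject (CAD, whole)",
      23745, round_half_up(expected_value(test, u)))
  add("net savings per detected case (CAD)",
      115000,
      net_savings_per_detection(params$annual_care_savings,
                                params$delay_years, params$scan_cost,
                                1 / test$p))

  co <- config$cost
  cost <- scan_cost_per_procedure(co$probe_cost_per_session,
                                  co$equipment_capital, co$depreciation_years,
                                  co$service_fraction, co$operating_cost,
                                  co$interpretation_cost, co$throughput)
  add("per-scan cost (CAD, truncated)", 1136, cost$printed)
  add("per-scan cost at or below assumed price", params$scan_cost,
      cost$total, "<=")
  add("buffer infrastructure value (million CAD)", 26,
      buffer_infrastructure_value(co$buffer, co$throughput,
                                  co$depreciation_years)$millions)

  t3 <- load_fixture("table3_incidence")
  t3 <- t3[t3$region %in% c("Canada", "USA", "China") & t3$year == 2020, ]
  dm <- config$demand
  cap <- capacity_table(
    data.frame(region = t3$region, age_range = t3$age_group,
               incidence = t3$count * 1000),
    lifestyle_fraction = dm$lifestyle_fraction,
    screening_multiplier = dm$screening_multiplier,
    rescreen_interval_years = dm$rescreen_interval_years,
    throughput = dm$throughput)
  expected_scanners <- c(`Canada 60-79` = 103, `Canada 60+` = 218,
                         `USA 60-79` = 850, `USA 60+` = 1742,
                         `China 60-79` = 2848, `China 60+` = 3942)
  for (nm in names(expected_scanners)) {
    parts <- strsplit(nm, " ")[[1]]
    row <- cap[cap$region == parts[1] & cap$age_range == parts[2], ]
    add(paste("scanner fleet,", nm), unname(expected_scanners[nm]),
        row$scanners)
  }
  totals <- attr(cap, "totals")
  add("total scanners, 60-79", 3801,
      totals$scanners[totals$age_range == "60-79"])
  add("total scanners, 60+", 5902, totals$scanners[totals$age_range == "60+"])
  add("screened per year, 60-79, three countries", 11405000,
      totals$screened[totals$age_range == "60-79"])

  ra <- config$radiation
  add("induced cancers per million at 7 mSv", 420,
      radiation_risk(ra$effective_dose_high, ra$risk_coefficient))
  add("induced cancers per million at 1 mSv", 60,
      radiation_risk(ra$effective_dose_low, ra$risk_coefficient))

  bc <- config$business
  case <- business_case(bc$fleet_target, bc$ramp_years, bc$product_life_years,
                        bc$unit_price, bc$service_fraction)
  add("units sold per year (presented)", 600, case$units_per_year)
  add("total annual revenue at maturity (USD)", 1.2e9,
      case$total_revenue_at_maturity)

  t1 <- load_fixture("table1_population")
  w60 <- t1[t1$region == "World" & t1$age_group == "60+", ]
  add("world 60+ growth 2010-2030 (%)", 82.8,
      percent_increase(w60$count[w60$year == 2010],
                       w60$count[w60$year == 2030]))
  t2 <- load_fixture("table2_prevalence")
  t3all <- load_fixture("table3_incidence")
  add("Canada 2020 incidence/prevalence ratio (%)", 20.5,
      incidence_prevalence_ratio(
        t3all$count[t3all$region == "Canada" & t3all$age_group == "60+" &
                      t3all$year == 2020] * 1000,
        t2$count[t2$region == "Canada" & t2$year == 2020] * 1000))

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  class(out) <- c("headline_report", "data.frame")
  out
}

#' @export
print.headline_report <- function(x, ...) {
  cat(sprintf("<headline_report> %d checks, %d pass\n", nrow(x), sum(x$pass)))
  df <- as.data.frame(x)
  df$expected <- format(df$expected, big.mark = ",", scientific = FALSE)
  df$computed <- format(df$computed, big.mark = ",", scientific = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
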