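# Per-scan cost model, screening demand, scanner fleet, radiation risk and
# the manufacturer's business case.

#' Per-procedure cost of a hybrid PET/MRI screening examination
#'
#' Component build-up per examination: probe cost, straight-line capital
#' depreciation per exam, annual service contract per exam, operating cost,
#' physician interpretation, plus an optional buffer for unspecified
#' infrastructure. Capital components are spread over
#' `throughput` examinations per year.
#'
#' @param probe_cost_per_session currency; radiotracer cost per exam (a
#'   production run split across the subjects imaged from it).
#' @param equipment_capital currency; PET insert plus MRI system.
#' @param depreciation_years straight-line depreciation horizon.
#' @param service_fraction service contract as a fraction of capital per year.
#' @param operating_cost currency per exam.
#' @param interpretation_cost currency per exam.
#' @param throughput examinations per scanner per year (> 0).
#' @param buffer currency per exam for unspecified costs (default 0).
#' @return List with `total` (full precision), `printed` (truncated to whole
#'   currency units, the form quoted in cost tables) and a component
#'   `breakdown` data frame.
#' @examples
#' scan_cost_per_procedure()$printed # 1136
#' @export
scan_cost_per_procedure <- function(probe_cost_per_session = 500,
                                    equipment_capital = 4.3e6,
                                    depreciation_years = 10,
                                    service_fraction = 0.10,
                                    operating_cost = 100,
                                    interpretation_cost = 250,
                                    throughput = 3000,
                                    buffer = 0) {
  stop_if_not_number(throughput, "throughput", lower = 0, strict_lower = TRUE)
  for (nm in c("probe_cost_per_session", "equipment_capital",
               "depreciation_years", "service_fraction", "operating_cost",
               "interpretation_cost", "buffer")) {
    stop_if_not_number(get(nm), nm, lower = 0)
  }
  depreciation <- if (depreciation_years > 0) {
    equipment_capital / depreciation_years / throughput
  } else 0
  service <- equipment_capital * service_fraction / throughput
  components <- c(probe = probe_cost_per_session, depreciation = depreciation,
                  service = service, operating = operating_cost,
                  interpretation = interpretation_cost, buffer = buffer)
  total <- sum(components)
  list(total = total, printed = trunc(total),
       breakdown = data.frame(component = names(components),
                              cost = unname(components)))
}

#' Infrastructure value implied by a per-exam cost buffer
#'
#' A per-examination buffer, attributed to equipment and laboratory
#' infrastructure depreciated straight-line, corresponds to a capital value
#' of `buffer * throughput * years`.
#'
#' @param buffer currency per examination.
#' @param throughput examinations per year.
#' @param years depreciation horizon.
#' @return List with `value` (exact product) and `millions` (value rounded
#'   half-up to the nearest million).
#' @examples
#' buffer_infrastructure_value(864, 3000, 10)$millions # 26
#' @export
buffer_infrastructure_value <- function(buffer, throughput, years) {
  for (nm in c("buffer", "throughput", "years")) {
    stop_if_not_number(get(nm), nm, lower = 0)
  }
  value <- buffer * throughput * years
  list(value = value, millions = round_half_up(value / 1e6))
}

#' Annual screening demand from annual incidence
#'
#' Persons to screen per year: annual incident cases, restricted to the
#' lifestyle-attributable fraction, multiplied by the number of screens
#' needed per future case (`1 / p`), divided by the rescreen interval.
#'
#' @param incidence_per_year annual incident dementia cases in the target
#'   age range.
#' @param lifestyle_fraction share of incidence attributable to modifiable
#'   lifestyle risk factors, in \[0, 1\] (default 0.5).
#' @param screening_multiplier screens per detected future case (default 10,
#'   i.e. prevalence 0.1 in the screened pool).
#' @param rescreen_interval_years years between screens of one person
#'   (default 1).
#' @return Persons to screen per year.
#' @examples
#' screening_demand(62000) # 310000
#' @export
screening_demand <- function(incidence_per_year, lifestyle_fraction = 0.5,
                             screening_multiplier = 10,
                             rescreen_interval_years = 1) {
  stop_if_not_number(incidence_per_year, "incidence_per_year", lower = 0)
  stop_if_not_number(lifestyle_fraction, "lifestyle_fraction", lower = 0, upper = 1)
  stop_if_not_number(screening_multiplier, "screening_multiplier", lower = 1)
  stop_if_not_number(rescreen_interval_years, "rescreen_interval_years", lower = 1)
  incidence_per_year * lifestyle_fraction * screening_multiplier /
    rescreen_interval_years
}

#' Scanner fleet needed for a screening volume
#'
#' `screened / throughput`, rounded half-up to a whole number of scanners
#' (the convention consistent with published fleet tables).
#'
#' @param screened_per_year persons screened per year.
#' @param throughput examinations per scanner per year (> 0).
#' @return Integer number of scanners.
#' @examples
#' scanner_fleet(655000) # 218
#' @export
scanner_fleet <- function(screened_per_year, throughput = 3000) {
  stop_if_not_number(screened_per_year, "screened_per_year", lower = 0)
  stop_if_not_number(throughput, "throughput", lower = 0, strict_lower = TRUE)
  as.integer(round_half_up(screened_per_year / throughput))
}

#' Radiation-induced cancers under the linear no-threshold model
#'
#' `effective_dose * risk_coefficient * per`: induced cancers per `per`
#' subjects screened, proportional to dose at all doses.
#'
#' @param effective_dose Sv per examination.
#' @param risk_coefficient induced cancers per Sv (default `6e-2`).
#' @param per population denominator (default one million screened).
#' @return Expected induced cancers per `per` subjects.
#' @examples
#' radiation_risk(7e-3) # 420 per million at 7 mSv
#' radiation_risk(1e-3) # 60 per million at 1 mSv
#' @export
radiation_risk <- function(effective_dose, risk_coefficient = 6e-2, per = 1e6) {
  for (nm in c("effective_dose", "risk_coefficient", "per")) {
    stop_if_not_number(get(nm), nm, lower = 0)
  }
  effective_dose * risk_coefficient * per
}

#' Manufacturer's business case for a scanner fleet
#'
#' Units sold per year are the fleet target spread over the ramp-up period;
#' the figure is presented rounded to the nearest hundred units. At market
#' maturity the installed base under service contract is
#' `units_per_year * product_life_years`, each unit paying
#' `unit_price * service_fraction` per year.
#'
#' @param fleet_target scanners needed (> 0).
#' @param ramp_years years to ramp up production (> 0).
#' @param product_life_years service life of a unit (> 0).
#' @param unit_price currency per unit (> 0).
#' @param service_fraction annual service contract as fraction of price.
#' @return List with presented figures (`units_per_year`, `gross_sales`,
#'   `service_revenue_at_maturity`, `total_revenue_at_maturity`, computed
#'   from the rounded unit count) and exact counterparts (`*_exact`,
#'   computed from `fleet_target / ramp_years` unrounded).
#' @examples
#' business_case(5902)$total_revenue_at_maturity # 1.2e9
#' @export
business_case <- function(fleet_target, ramp_years = 10,
                          product_life_years = 10, unit_price = 1e6,
                          service_fraction = 0.10) {
  stop_if_not_number(fleet_target, "fleet_target", lower = 0)
  for (nm in c("ramp_years", "product_life_years", "unit_price")) {
    stop_if_not_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  stop_if_not_number(service_fraction, "service_fraction", lower = 0)
  units_exact <- fleet_target / ramp_years
  units <- round_half_up(units_exact / 100) * 100
  rev <- function(u) {
    gross <- u * unit_price
    service <- u * product_life_years * unit_price * service_fraction
    c(gross = gross, service = service, total = gross + service)
  }
  pres <- rev(units); exact <- rev(units_exact)
  list(units_per_year = units,
       gross_sales = unname(pres["gross"]),
       service_revenue_at_maturity = unname(pres["service"]),
       total_revenue_at_maturity = unname(pres["total"]),
       units_per_year_exact = units_exact,
       gross_sales_exact = unname(exact["gross"]),
       service_revenue_at_maturity_exact = unname(exact["service"]),
       total_revenue_at_maturity_exact = unname(exact["total"]))
}

#' Screening-capacity table for a set of regions
#'
#' For each region/age-range row of annual incidence, derives the
#' lifestyle-attributable pool, the annual screening volume and the scanner
#' fleet required, in the layout of published capacity tables.
#'
#' @param incidence data frame with columns `region`, `age_range`,
#'   `incidence` (annual incident cases).
#' @param lifestyle_fraction,screening_multiplier,rescreen_interval_years
#'   passed to [screening_demand()].
#' @param throughput passed to [scanner_fleet()].
#' @return The input with added columns `lifestyle_pool`, `screened`,
#'   `scanners`, plus an attribute `"totals"`: a data frame of summed
#'   `screened` and `scanners` per `age_range`.
#' @examples
#' capacity_table(data.frame(region = "Canada", age_range = "60-79",
#'                           incidence = 62000))
#' @export
capacity_table <- function(incidence, lifestyle_fraction = 0.5,
                           screening_multiplier = 10,
                           rescreen_interval_years = 1, throughput = 3000) {
  stopifnot(all(c("region", "age_range", "incidence") %in% names(incidence)))
  out <- as.data.frame(incidence)
  out$lifestyle_pool <- out$incidence * lifestyle_fraction
  out$screened <- vapply(out$incidence, screening_demand, numeric(1),
                         lifestyle_fraction = lifestyle_fraction,
                         screening_multiplier = screening_multiplier,
                         rescreen_interval_years = rescreen_interval_years)
  out$scanners <- vapply(out$screened, scanner_fleet, integer(1),
                         throughput = throughput)
  totals <- aggregate(cbind(screened, scanners) ~ age_range, data = out, FUN = sum)
  attr(out, "totals") <- totals
  out
}
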