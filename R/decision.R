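# Expected-value model of the screening test.
#
# A screened subject falls into one of four outcome classes — true positive,
# false positive, true negative, false negative — with probabilities induced
# by the test's sensitivity/specificity and the prevalence of future
# dementia in the screened pool. Each class carries a currency-valued
# consequence (the utility matrix); the expected value is their
# probability-weighted sum per screened subject.

#' Screening test characteristics
#'
#' @param se sensitivity, in (0, 1]: probability of a positive test given
#'   future dementia.
#' @param sp specificity, in (0, 1]: probability of a negative test given no
#'   future dementia.
#' @param p prevalence of future dementia in the screened population, in
#'   \[0, 1\].
#' @return Object of class `test_characteristics` with the four outcome
#'   fractions `tpf = se`, `fnf = 1 - se`, `tnf = sp`, `fpf = 1 - sp`.
#' @examples
#' test_characteristics(0.9, 0.9, 0.1)
#' @export
test_characteristics <- function(se = 0.9, sp = 0.9, p = 0.1) {
  stop_if_not_number(se, "se", lower = 0, upper = 1, strict_lower = TRUE)
  stop_if_not_number(sp, "sp", lower = 0, upper = 1, strict_lower = TRUE)
  stop_if_not_number(p, "p", lower = 0, upper = 1)
  structure(list(se = se, sp = sp, p = p,
                 tpf = se, fnf = 1 - se, tnf = sp, fpf = 1 - sp),
            class = "test_characteristics")
}

#' Economic parameters of the screening decision model
#'
#' Monetary inputs for the utility matrix. The willingness to pay per QALY
#' is quoted in base-year USD and converted to analysis-year CAD through an
#' inflation factor and an exchange rate. The QALY weight is the
#' quality-of-life difference between the non-demented and demented states.
#' Therapy cost may be given per year (`therapy_cost_annual`, scaled by the
#' delay length) or overridden as a fixed total (`therapy_cost_total`).
#'
#' @param wtp_base willingness to pay per QALY, currency of the base year.
#' @param inflation_factor cumulative inflation, base year to analysis year.
#' @param fx_rate analysis currency per base currency (CAD per USD).
#' @param qaly_weight QALY difference between health states, in \[0, 1\].
#' @param delay_years onset delay attributed to a detected case.
#' @param annual_care_savings averted care cost, currency/person/year.
#' @param therapy_cost_annual therapy cost, currency/person/year.
#' @param therapy_cost_total total therapy cost over the delay period;
#'   defaults to `therapy_cost_annual * delay_years`.
#' @param scan_cost price of one screening examination.
#' @param discount_rate annual discount rate applied to the care-savings and
#'   QALY streams (default 0: streams are summed undiscounted).
#' @param fn_penalty optional extra cost attached to a missed case
#'   (default 0: a false negative carries only the scan cost).
#' @return Object of class `economic_params`.
#' @examples
#' economic_params() # reference analysis defaults
#' @export
economic_params <- function(wtp_base = 80000, inflation_factor = 1.10,
                            fx_rate = 1.3, qaly_weight = 0.348,
                            delay_years = 5, annual_care_savings = 27000,
                            therapy_cost_annual = 4800,
                            therapy_cost_total = therapy_cost_annual * delay_years,
                            scan_cost = 2000, discount_rate = 0,
                            fn_penalty = 0) {
  stop_if_not_number(wtp_base, "wtp_base", lower = 0)
  stop_if_not_number(inflation_factor, "inflation_factor", lower = 0)
  stop_if_not_number(fx_rate, "fx_rate", lower = 0)
  stop_if_not_number(qaly_weight, "qaly_weight", lower = 0, upper = 1)
  stop_if_not_number(delay_years, "delay_years", lower = 0)
  stop_if_not_number(annual_care_savings, "annual_care_savings", lower = 0)
  stop_if_not_number(therapy_cost_annual, "therapy_cost_annual", lower = 0)
  stop_if_not_number(therapy_cost_total, "therapy_cost_total", lower = 0)
  stop_if_not_number(scan_cost, "scan_cost", lower = 0)
  stop_if_not_number(discount_rate, "discount_rate", lower = 0)
  stop_if_not_number(fn_penalty, "fn_penalty", lower = 0)
  structure(list(wtp_base = wtp_base, inflation_factor = inflation_factor,
                 fx_rate = fx_rate, qaly_weight = qaly_weight,
                 delay_years = delay_years,
                 annual_care_savings = annual_care_savings,
                 therapy_cost_annual = therapy_cost_annual,
                 therapy_cost_total = therapy_cost_total,
                 scan_cost = scan_cost, discount_rate = discount_rate,
                 fn_penalty = fn_penalty),
            class = "economic_params")
}

#' Annual monetary value of the QALY difference
#'
#' `wtp_base * inflation_factor * fx_rate * qaly_weight`: the willingness to
#' pay per QALY, brought to analysis-year CAD, times the quality-of-life
#' difference between the non-demented and demented states. At the defaults
#' this is `80000 * 1.10 * 1.3 * 0.348 = 39811.2` CAD per year of delayed
#' onset.
#'
#' @param params an [economic_params()].
#' @return Currency per year.
#' @examples
#' qaly_annual_value(economic_params()) # 39811.2
#' @export
qaly_annual_value <- function(params) {
  stopifnot(inherits(params, "economic_params"))
  params$wtp_base * params$inflation_factor * params$fx_rate * params$qaly_weight
}

# sum of a one-per-year stream over the delay period, optionally discounted
stream_factor <- function(params) {
  d <- params$delay_years
  r <- params$discount_rate
  if (r == 0) return(d)
  if (d == 0) return(0)
  whole <- floor(d)
  f <- if (whole > 0) sum((1 + r)^-(seq_len(whole))) else 0
  f + (d - whole) * (1 + r)^-(whole + 1)   # pro-rata fractional final year
}

#' Utility matrix of screening outcomes
#'
#' Currency-valued consequences per screened subject:
#' * `u_tp` — a detected future case: care savings and QALY value accrue for
#'   each year of delayed onset, less therapy and scan cost;
#' * `u_fp` — a false alarm: therapy and scan cost, no benefit;
#' * `u_tn`, `u_fn` — scan cost only (a missed case carries no additional
#'   penalty by construction; `fn_penalty` can add one).
#'
#' @param params an [economic_params()].
#' @return Object of class `utility_matrix` with fields `u_tp`, `u_fp`,
#'   `u_tn`, `u_fn`.
#' @examples
#' build_utility_matrix(economic_params()) # u_tp = 308056
#' @export
build_utility_matrix <- function(params) {
  stopifnot(inherits(params, "economic_params"))
  f <- stream_factor(params)
  u_tp <- params$annual_care_savings * f + qaly_annual_value(params) * f -
    params$therapy_cost_total - params$scan_cost
  u_fp <- -params$therapy_cost_total - params$scan_cost
  u_tn <- -params$scan_cost
  u_fn <- -params$scan_cost - params$fn_penalty
  structure(list(u_tp = u_tp, u_fp = u_fp, u_tn = u_tn, u_fn = u_fn),
            class = "utility_matrix")
}

#' @export
print.utility_matrix <- function(x, ...) {
  cat("<utility_matrix> (currency per screened subject)\n")
  cat(sprintf("  U(TP) = %12.2f\n  U(FP) = %12.2f\n  U(TN) = %12.2f\n  U(FN) = %12.2f\n",
              x$u_tp, x$u_fp, x$u_tn, x$u_fn))
  invisible(x)
}

#' Expected value of the screening test per screened subject
#'
#' The probability-weighted sum of the utility matrix:
#' `E = U(TP) se p + U(FP) (1-sp)(1-p) + U(TN) sp (1-p) + U(FN) (1-se) p`.
#' At the reference defaults (se = sp = 0.9, p = 0.1) this is
#' $23,745.04, printed as $23,745.
#'
#' @param test a [test_characteristics()].
#' @param u a [utility_matrix()][build_utility_matrix].
#' @return Currency per screened subject (full precision; round for display).
#' @examples
#' expected_value(test_characteristics(), build_utility_matrix(economic_params()))
#' @export
expected_value <- function(test, u) {
  stopifnot(inherits(test, "test_characteristics"),
            inherits(u, "utility_matrix"))
  u$u_tp * test$tpf * test$p +
    u$u_fp * test$fpf * (1 - test$p) +
    u$u_tn * test$tnf * (1 - test$p) +
    u$u_fn * test$fnf * test$p
}

#' Net savings per detected case
#'
#' Gross care savings over the delay period minus the imaging cost of
#' finding one case (`scan_cost * screens_per_detection`, where
#' `screens_per_detection = 1 / p`).
#'
#' @param annual_care_savings currency/person/year.
#' @param delay_years years of delayed onset.
#' @param scan_cost currency per examination.
#' @param screens_per_detection examinations needed per detected case (>= 1).
#' @return Currency per detected case.
#' @examples
#' net_savings_per_detection(27000, 5, 2000, 10) # 115000
#' @export
net_savings_per_detection <- function(annual_care_savings = 27000,
                                      delay_years = 5, scan_cost = 2000,
                                      screens_per_detection = 10) {
  stop_if_not_number(screens_per_detection, "screens_per_detection", lower = 1)
  annual_care_savings * delay_years - scan_cost * screens_per_detection
}

#' Expected value as a function of the achieved onset delay
#'
#' Re-evaluates the decision model at delay `d`: care savings and QALY
#' streams accrue for `d` years and therapy cost scales as
#' `therapy_cost_annual * d`, so with zero discounting `E(d)` is affine in
#' `d` and `E(0)` retains only the scan cost. At the reference defaults the
#' expected value crosses zero near `d = 0.39` years.
#'
#' @param test a [test_characteristics()].
#' @param params an [economic_params()] (its `delay_years` and
#'   `therapy_cost_total` are replaced).
#' @param d onset delay in years (vectorised, >= 0).
#' @return Currency per screened subject, one value per element of `d`.
#' @examples
#' expected_value_vs_delay(test_characteristics(), economic_params(), c(0, 5))
#' @export
expected_value_vs_delay <- function(test, params, d) {
  stopifnot(inherits(params, "economic_params"))
  vapply(d, function(di) {
    stop_if_not_number(di, "d", lower = 0)
    p2 <- params
    p2$delay_years <- di
    p2$therapy_cost_total <- params$therapy_cost_annual * di
    expected_value(test, build_utility_matrix(p2))
  }, numeric(1))
}
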