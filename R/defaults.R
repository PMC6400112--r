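#' Default model parameters
#'
#' All published default values used across the package, collected in one
#' place so no numeric literal is scattered through the code. Each block
#' corresponds to one model layer; every entry records units and meaning.
#'
#' The defaults describe the reference analysis: screening adults with
#' lifestyle risk factors using a hybrid PET/MRI test with sensitivity and
#' specificity 0.9 in a screened population with prevalence 0.1, valuing a
#' five-year delay of dementia onset through annual care savings of
#' $27,000 CAD and a monetised QALY difference of 0.348 between non-demented
#' and demented states (willingness to pay $80,000 USD in 2011 dollars,
#' inflated by 1.10 and converted at 1.30 CAD/USD), against a therapy cost
#' of $4,800 CAD/year and a $2,000 CAD scan price.
#'
#' @return A named list with blocks `economic`, `test`, `cost`, `demand`,
#'   `radiation`, `business`, `delay`, `demographic`.
#' @examples
#' default_parameters()$economic$wtp_base
#' @export
default_parameters <- function() {
  list(
    economic = list(
      wtp_base            = 80000,   # willingness to pay per QALY, USD, 2011 dollars
      inflation_factor    = 1.10,    # cumulative inflation 2011 -> analysis year
      fx_rate             = 1.30,    # CAD per USD
      qaly_weight         = 0.348,   # QALY difference, non-demented vs demented
      delay_years         = 5,       # assumed onset delay achieved in detected cases
      annual_care_savings = 27000,   # CAD/person/year of delayed onset
      therapy_cost_annual = 4800,    # CAD/person/year (upper-limit drug estimate)
      scan_cost           = 2000,    # CAD per screening examination (price charged)
      discount_rate       = 0,       # annual; streams summed undiscounted by default
      fn_penalty          = 0        # optional extra cost attached to a missed case
    ),
    test = list(
      se = 0.9,                      # sensitivity
      sp = 0.9,                      # specificity
      p  = 0.1                       # prevalence of future dementia in screened pool
    ),
    cost = list(
      probe_cost_per_session = 500,     # CAD; probe production run split over 10 scans
      equipment_capital      = 4.3e6,   # CAD; brain PET insert (1.3M) + 3T MRI (3M)
      depreciation_years     = 10,      # straight-line
      service_fraction       = 0.10,    # of capital, per year
      operating_cost         = 100,     # CAD per examination
      interpretation_cost    = 250,     # CAD per examination (physician reading)
      throughput             = 3000,    # examinations per scanner per year
      buffer                 = 864      # CAD/exam unspecified-infrastructure buffer
    ),
    demand = list(
      lifestyle_fraction      = 0.5,   # share of incidence attributable to lifestyle
      screening_multiplier    = 10,    # screens per future case (1/p at p = 0.1)
      throughput              = 3000,  # examinations per scanner per year
      rescreen_interval_years = 1
    ),
    radiation = list(
      effective_dose_high = 7e-3,   # Sv/exam, whole-body PET/MRI reference
      effective_dose_low  = 1e-3,   # Sv/exam, optimised head-only system
      risk_coefficient    = 6e-2    # induced cancers per Sv (linear no-threshold)
    ),
    business = list(
      fleet_target       = 5902,    # scanners (60+ screening, three countries)
      ramp_years         = 10,
      product_life_years = 10,
      unit_price         = 1e6,     # USD per unit
      service_fraction   = 0.10     # of sale price, per year
    ),
    delay = list(
      delay_years          = 5,
      care_fraction        = 261 / 340,  # share of prevalent cases receiving care
      annual_cost_per_case = 27000       # CAD/person/year direct care cost
    ),
    demographic = list(
      incidence_anchor_age     = 62,    # midpoint of the 60-64 band
      incidence_anchor_rate    = 3.9,   # per 1000 person-years at 60-64
      incidence_doubling_years = 6.3    # incidence doubles per this many years of age
    )
  )
}
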