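Package: demscreen
Title: Cost-Benefit Modelling of Population Dementia Screening with Hybrid PET/MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic tools for evaluating a population screening
    programme for lifestyle-attributable dementia using hybrid PET/MRI.
    Provides demographic projection of dementia prevalence and incidence
    from age-banded population tables, a deterministic cohort model of the
    effect of delaying dementia onset, an expected-value model of the
    screening test built from a currency-valued utility matrix and
    QALY/willingness-to-pay valuation, per-scan cost and scanner-fleet
    capacity planning with a linear no-threshold radiation-risk estimate,
    one-way/threshold/probabilistic sensitivity analysis, and a synthetic
    scenario generator for age-structured populations with age-doubling
    dementia incidence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
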