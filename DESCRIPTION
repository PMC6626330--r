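Package: residhu
Title: Residual-Based Identification of High Health-Care Utilizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk-adjusts per-member per-month health-care expenditures on
    clinical and demographic factors (ordinary least squares and gradient
    boosted trees on log10-transformed cost), identifies "impactable" high
    utilizers as the consistently deviating right tail of the residual
    distribution on the normal Q-Q scale, and characterizes that population:
    demographic/comorbidity profiles, year-to-year persistence of residual
    rank percentiles, decomposition of residual-associated spending to
    individual diagnosis codes, and setting-stratified models linked to
    potentially preventable readmissions and emergency-department visits.
    Includes a synthetic multi-year claims generator with planted, persistent
    excess utilization so the full pipeline is testable without protected
    health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest
Config/testthat/edition: 3
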