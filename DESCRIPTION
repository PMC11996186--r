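Package: aicm
Title: Indirect Estimation of Induced Abortions from Hospital Admission Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the incidence of induced abortion from administrative
    hospital-admission microdata using the Abortion Incidence Complications
    Method (AICM). Implements ICD-10 case selection in public-sector (SIH/SUS
    style) discharge records and private-insurance (ANS style) claims with
    event-level linkage and deduplication, insurance-coverage denominators,
    age-specific miscarriage correction, scenario-based calibration of the
    non-hospitalization correction factor against a national survey total,
    and the resulting abortion counts, rates per 1,000 women of reproductive
    age and ratios per 100 live births with sensitivity bounds. Ships a
    seeded synthetic-microdata generator whose aggregates match configurable
    region-by-age margins so the whole pipeline is testable without access
    to the source data systems.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
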