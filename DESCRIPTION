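Package: iimcohort
Title: Incident Myositis Cohorts and Outcome Incidence Rates from Longitudinal Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds natural-history study populations for idiopathic inflammatory
    myopathies (dermatomyositis and polymyositis, adult and juvenile) from
    longitudinal patient-level health-record tables. Identifies incident cases
    with a weighted exposure-assessment-window phenotyping algorithm, assigns
    disease subtype with deterministic tie-breaking, samples birth-year- and
    sex-matched controls without replacement, derives per-outcome washout
    eligibility and censored follow-up, and estimates crude incidence rates per
    100 person-years with exact Poisson (Garwood) confidence intervals. Includes
    a calibrated synthetic claims-data generator with known ground truth so that
    every pipeline stage can be validated end-to-end without access to
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
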