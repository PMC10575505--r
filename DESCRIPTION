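Package: capquality
Title: Quality Classification of Outpatient Antibiotic Prescribing for
    Community-Acquired Pneumonia in Older Adults
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds acute community-acquired pneumonia (CAP) episodes of care
    from administrative claims (physician visits, drug dispensations, hospital
    admissions), links the first antibiotic dispensation to each episode, and
    classifies every linked prescription into one of five mutually exclusive
    quality categories (guideline adherent, clinically appropriate, effective
    but unnecessary, undertreatment, not recommended) using configurable
    first-line agent rules, daily-dose bounds, comorbidity code lists and the
    Charlson comorbidity index.  Provides Poisson rate-ratio trend analysis
    with an annual population offset, age-standardised rates per 1000, duration
    and ATC-class summaries with small-cell suppression, and a synthetic
    claims generator with known ground truth so the whole pipeline is testable
    without access to restricted provincial databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
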