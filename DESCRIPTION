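Package: ubtimpact
Title: Cohort Impact Modelling of Uterine Balloon Tamponade for Postpartum Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic cohort treatment-cascade model of postpartum
    hemorrhage (PPH) care in sub-Saharan Africa, used to estimate the lives
    saved, surgeries averted, severe hemorrhage cases averted and severe
    anemia cases prevented by introducing a low-cost uterine balloon
    tamponade (UBT) in clinic and hospital deliveries. Provides scenario and
    one-way sensitivity analysis, calibration of the cascade's unpublished
    internal parameters (uterotonic efficacy, severity progression, surgical
    access, case fatality) to published aggregate outputs via multi-start
    bounded least squares, identifiability profiling, a seeded
    individual-level microsimulation oracle that shares the cascade's branch
    structure, and YAML-configured command wrappers with CSV reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    lhs,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
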