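Package: cyclehealth
Title: Menstrual Cycle Status Classification, Monitoring Plans, and
    Synthetic Self-Tracking Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic, auditable rule engine for menstrual health
    monitoring. Segments longitudinal self-monitoring event logs (bleed
    days, urinary LH tests, basal body temperature, mid-luteal serum
    progesterone, cervical mucus, symptoms, contraception records) into
    cycles, classifies cycle status with published decision trees and
    threshold criteria (eumenorrheic, luteal phase defect, anovulatory,
    oligomenorrheic, amenorrheic), models hormonal contraception regimens
    and their monitoring compatibility, generates dated monitoring plans
    at recommended frequencies, and simulates seeded synthetic event logs
    with ground truth for every hormonal phenotype so that every decision
    path is testable without real health data. Classification respects a
    monitoring-tier cap so that evidence beyond a chosen privacy level is
    never read. The engine emits medical-review flags only; it is not a
    diagnostic tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
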