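Package: canalarea
Title: Cervical Spinal Canal Area Approximation from Linear CT Measurements
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Approximates the cross-sectional area of the cervical central
    canal (C2-3 to C6-7) from two linear CT measurements, the anteroposterior
    (AP) diameter and the interpedicular distance (IPD), using closed-form
    ellipse, triangle and rectangle models and per-level second-order
    approximations (full ellipse value plus a small fitted fraction of the
    rectangle value). Provides the agreement machinery used to judge such
    approximations against manually traced areas (paired mean differences,
    percent error, Pearson correlation with weak/moderate/strong banding,
    paired t-tests), a seeded synthetic-cohort generator calibrated to
    published normative level summaries so the whole pipeline is testable
    without patient data, and a report runner that writes the four standard
    summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
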