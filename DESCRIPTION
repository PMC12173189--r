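Package: cgmscreen
Title: Continuous-Growth-Model Microsimulation of Breast Cancer Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Natural-history microsimulation of breast cancer built on a
    continuous tumor growth model: a two-stage (MVK) carcinogenesis onset
    model, exponential tumor growth with a gamma-distributed inverse growth
    rate, and symptomatic detection with hazard proportional to tumor
    volume. Includes maximum-likelihood estimation of the growth and
    symptomatic-detection parameters from clinical tumor-size data via the
    Lomax-type marginal volume likelihood, an overlay of mammography
    screening policies (schedule, attendance mixture, size-dependent
    logistic sensitivity), and strategy-evaluation metrics (overdiagnosis,
    interval-cancer and screen-detection shares, tumor-size and
    doubling-time distributions). A synthetic clinical-data generator and a
    parameter-recovery harness make the full pipeline testable without
    access to patient records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
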