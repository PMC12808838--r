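Package: acuitybench
Title: Acuity-Adjusted Nurse Staffing Benchmarks for Neonatal Intensive Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Benchmarks registered-nurse staffing in neonatal intensive care
    units against acuity-adjusted recommendations. Classifies each infant
    care-day into intensive care, high-dependency care or special care from
    daily intervention flags via a configurable ordered rule table (an adapted
    three-level British Association of Perinatal Medicine scheme), accounts
    infant-hours and clinical staff-hours against fixed shift analysis windows
    (day 07:00-14:00, evening 14:00-21:00, night 21:00-07:00), computes the
    registered-nurse provision ratio per unit-shift with weights 1.0/0.5/0.25
    per acuity category, and summarises skill mix and weekday/weekend and
    shift-type contrasts with nonparametric tests. Includes a synthetic
    cohort and roster generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
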