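Package: schooldemand
Title: Leslie-Matrix Forecasting of School-Age Populations and Rural Teacher Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-component forecasting of school-age populations and the
    teacher demand they imply, for regions undergoing demographic decline and
    educational urbanization. Projects an age-structured female population with
    a Leslie matrix driven by crude birth- and death-rate trends, converts the
    projection to grade and stage enrollment with the grade-progression ratio
    method, splits enrollment into rural and urban shares with a linear
    rural-concentration model, and converts rural students to full-time teacher
    requirements via student-teacher staffing ratios. Includes a seeded
    synthetic-scenario generator emulating census-style inputs so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
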