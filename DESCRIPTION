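Package: telealert
Title: Alert-Burden Modelling for Home Blood-Pressure Telemonitoring Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a home blood-pressure telemonitoring cohort on a
    ladder of acute-to-chronic measurement protocols, generates simple,
    complex, overdue and inactive alerts with automatic versus manual
    routing, clusters manually processed alerts into per-user per-day
    e-nurse telemonitoring actions with an administrative/clinical
    workload model, and runs counterfactual alert-threshold scenario
    analyses that quantify alert reduction and nursing time savings.
    Includes Table-style descriptive summaries and a top-user
    alert-concentration (Lorenz) analysis for alert-fatigue review.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
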