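Package: prepostCEA
Title: Pre-Post Cost-Effectiveness Analysis of Psychosocial Care from
    Service Utilization and SF-12 Quality of Life
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for descriptive pre-post cost-utility analysis of
    psychosocial care programmes from a payer perspective. Costs service
    utilization records against a unit-cost table and aggregates them into
    per-user, per-client and total expenditures with normal-approximation
    confidence intervals; scores SF-12 responses into physical and mental
    component summaries, classifies them into SF-6D health states and values
    them with a pluggable additive-decrement preference tariff; estimates
    quality-adjusted life-years by the area-under-the-curve method with
    last-observation-carried-forward imputation of costs and utilities; and
    summarises cost-effectiveness with a client-level nonparametric bootstrap
    of the cost-effectiveness plane, incremental cost-effectiveness ratios or
    dominance classification, and cost-effectiveness acceptability curves.
    Includes a calibrated synthetic-cohort simulator so the whole pipeline is
    testable without access to confidential client data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
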