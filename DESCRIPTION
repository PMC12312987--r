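Package: fedstats
Title: Federated Statistical Analysis with Local Differential Privacy for
    Multi-Center Clinical Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a federation of hospital nodes that answer statistical
    queries on local patient-level tables under disclosure control and pure
    epsilon-differential-privacy (Laplace and exponential mechanisms, additive
    budget composition), with a coordinator that pools only aggregate messages.
    Includes a harmonized cohort data model for an oncology use case (first-line
    treatment duration and disease progression before and after the first
    COVID-19 wave), a synthetic multi-center cohort generator and a
    deterministic fixture reproducing the study's published marginals,
    federated descriptive statistics, contingency-table tests with automatic
    chi-square/Fisher selection, a differentially private two-sample t-test,
    federated linear regression via sufficient-statistic sharing, and a
    center-stratified Cox proportional hazards model fitted by distributed
    Newton-Raphson.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
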