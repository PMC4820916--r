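Package: lipidrisk
Title: Lipidomic Risk Scores for Incident Type 2 Diabetes in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Development and validation of plasma lipidomic risk scores (LRS)
    for incident type 2 diabetes from pedigree-structured cohort data.
    Provides pedigree relationship matrices, mixed-effects (kinship-frailty)
    Cox proportional hazards models with penalized partial likelihood,
    lipidome-wide survival screening with false-discovery-rate control,
    backward-elimination score construction, liability-threshold ROC curves
    for family data with Hanley-McNeil areas, incremental-value metrics
    (Uno's C, IDI, continuous NRI), Poisson person-time validation for
    cohorts without exact event dates, insulin-resistance index panels, and
    decision-analytic cost-effectiveness of screening-and-intervention
    strategies (tree rollback, ICER, net monetary benefit, tornado and
    microsimulation sensitivity analyses). A synthetic-cohort generator with
    planted effects supports end-to-end testing without access to restricted
    cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
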