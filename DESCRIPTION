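Package: ssbcea
Title: Cost-Effectiveness Modelling of Sugar-Sweetened-Beverage Portion-Size
    Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population health and economic consequences of two
    portion-size interventions on sugar-sweetened beverages (SSBs): a cap on
    single-serve package sizes and reformulation to a reduced energy density.
    Intervention scenarios are translated into per-stratum changes in daily
    energy intake, converted to steady-state body-weight and BMI changes, and
    propagated through a proportional multi-state, multiple-cohort life table
    covering nine obesity-related diseases to obtain health-adjusted life
    years (HALYs), health-care cost offsets, and incremental
    cost-effectiveness ratios with Monte Carlo uncertainty intervals. A
    seeded synthetic-data generator supplies population, epidemiology,
    consumption and package-size sales-share bundles with the statistical
    structure the analysis assumes.
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
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
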