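Package: csascen
Title: Desk-Scale Climate-Smart Agriculture Scenario Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded synthetic-world pipeline for exploring global
    climate-smart agriculture (CSA) adoption scenarios at desk scale:
    gridded crop production with practice responses, yield-based and
    emission-intensity-based adoption rules, quartile tailoring of
    food-production-unit yield shifters, a constant-elasticity
    multi-region partial-equilibrium commodity market, IPCC Tier-1
    cropland greenhouse-gas accounting (direct N2O emission factors,
    rice CH4 water-regime and organic-amendment scaling, soil organic
    carbon offsets), and food-security indicators (kilocalorie
    availability, population at risk of hunger, undernourished
    children).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
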