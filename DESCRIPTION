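Package: soilrisk
Title: Health Risk Assessment for Metal-Contaminated Soils with Censored
    Concentration Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening-level human health risk assessment of
    metal-contaminated surface soils, built around the data realities of
    field geochemistry: left-censored ("<LOD") concentrations summarised by
    Kaplan-Meier product-limit statistics, Peto-Peto group comparisons,
    enrichment-factor and geoaccumulation pollution indices with standard
    descriptive classes, soil-guideline exceedance screening, in vitro
    bioaccessibility conversion to relative bioavailability, and oral-ingestion
    exposure arithmetic (chemical daily intake, hazard quotients and index,
    arsenic cancer risk). A seeded synthetic-data generator emulates the
    multi-element, source-structured, spatially decaying concentration patterns
    of an e-waste recycling site so the whole pipeline is testable end to end
    without external data.
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
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
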