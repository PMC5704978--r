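Package: zipranks
Title: ZIP-Level Population Health Indices in the County Health Rankings Framework
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds County Health Rankings (CHR)-style Health Factors and
    Health Outcomes indices at the ZIP code level from hospital- and
    census-derived measures, and evaluates them against county reference
    scores. Provides measure screening (standardization, skew handling,
    correlation-based retention), principal-component subdomain analog
    scores, county-calibrated domain regressions whose weights transfer to
    ZIP level, population-weighted ZIP-to-county apportionment via
    Geocorr-style crosswalks, random-intercept variance decomposition
    (intraclass correlation and BLUP shrinkage predictions), and
    ranking-agreement evaluation (quintile cross-classification, weighted
    kappa, within-band agreement). Includes a calibrated two-level synthetic
    data generator with known ground truth so every stage is testable
    without proprietary discharge or commercial census products.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
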