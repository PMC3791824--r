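Package: childdqi
Title: Child Diet Quality Scoring with the HEI-2005 and the RC-DQI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores two-day average dietary intakes of children aged 2-18
    years under two composite diet quality indexes: the Healthy Eating
    Index 2005 (12 components, 100 points, scored on a per-1000-kcal
    density basis with linear proration) and the Revised Children's Diet
    Quality Index (13 components, 90 points, age-indexed food-group and
    nutrient targets with proportional deduction). Implements the
    five-component comparison of the two indexes: rescaling the shared
    dairy, fruit, vegetable, total-grain and whole-grain components to
    0-5 points, a 0-25 subscore, within- and between-index Pearson
    correlation matrices with significance flags, score-distribution
    classes (minimum / intermediate / maximum), and stratification by
    age, ethnic and income group. A seeded generator of NHANES-like
    two-day recall datasets (zero-inflated gamma intakes with a shared
    latent diet-quality factor) supports end-to-end testing without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
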