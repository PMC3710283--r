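Package: poivalid
Title: Field Validation of Point-of-Interest Business Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating secondary point-of-interest databases
    (e.g. commercial food-outlet listings) against field census
    observations. Implements rule-based outlet categorization from
    industry classification codes and business-name keywords,
    deduplication, point-in-polygon assignment of records to areal units
    (census tracts), staged record matching with a disposition taxonomy
    (matched, name error, location error, category error, not found,
    unlisted, ill-extracted), traditional and relaxed sensitivity and
    positive predictive value, a representativity measure with
    within-unit within-category compensation between false positives and
    false negatives, weighted aggregation with confidence intervals,
    Pearson chi-square tests of variation across area groupings and
    outlet categories, and a seeded synthetic-foodscape simulator with
    closed-form expected metrics for parameter-recovery checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    stringi,
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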