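Package: pbodyscreen
Title: Suppressor-Screen, Expression-Filter and Genetic-Interaction Analysis
    for P-Body Mutants Under Replication Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the quantitative analysis chain of
    a yeast P-body / replication-stress study: colony-array suppressor-screen
    scoring (fitness ratios, per-plate Z-scores, replicate-averaged hit calls),
    differential-expression table filtering (Benjamini-Hochberg calls,
    consecutive-timepoint rules, HU-core set construction) and integration with
    screen hits, growth-curve fitness by area under the OD600 curve,
    multiplicative-model genetic-interaction scoring with drug-exacerbation
    tests, Bliss-style two-drug synergy matrices, and supporting enrichment and
    quantification statistics. A synthetic-data module generates every input
    with planted ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
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
    readr,
    rlang,
    stats,
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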