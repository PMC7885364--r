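Package: lumrewb
Title: Land-Use-Mix Exposure in Sausage Network Buffers and Within-Between
    Panel Models of Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes land-use-mix (LUM) entropy scores inside sausage
    network buffers around residential locations, harmonizes physical
    activity questionnaire outcomes (SQUASH, LAPAQ) to average minutes per
    week, and estimates within- and between-individual associations between
    land-use mix and walking or cycling with a random-effects within-between
    (REWB, hybrid/Mundlak) linear mixed model, including chained-equations
    multiple imputation of covariates with Rubin pooling. Ships a synthetic
    geospatial cohort generator (road network, evolving 11-class land-use
    mosaic, three-wave panel with known effects) so the whole pipeline is
    testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    lme4,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
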