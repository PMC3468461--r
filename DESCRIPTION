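Package: sonopt
Title: Orthogonal-Design Optimization of Ultrasound Seed Pretreatment
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for optimizing ultrasound (sonication) seed-pretreatment
    conditions from L16(4^5) orthogonal-array germination experiments.
    Implements Taguchi-style range analysis with optimal-level selection,
    factorial ANOVA with a vacancy-column error check, Student-Newman-Keuls
    compact letter displays, MANOVA test statistics from SSCP matrices,
    pairwise binary quadratic response-surface fits with stationary-point
    extraction, grouped-frequency mode aggregation of surface peaks into
    final recommended conditions, and logarithmic electrolyte-leakage
    models for seed-vigor conductivity assays. A synthetic-data generator
    emulates the replicate structure of dish-level germination counts
    (beta-binomial), seedling plumule/radicle lengths (truncated bivariate
    normal), and conductivity time series, so every analysis stage can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
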