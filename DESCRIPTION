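Package: cellprop
Title: Compositional Analysis of Single-Cell Cluster Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quality-control filtering of single-cell RNA-seq cells,
    cluster-by-condition proportion tables, clinical stratification of
    samples, and a permutation-based differential proportion analysis
    (DPA) in which cluster labels of a random fraction of cells are
    shuffled to build an empirical null distribution, with add-one
    empirical p-values and Bonferroni correction. Includes a synthetic
    cohort generator (Dirichlet-multinomial compositions, negative
    binomial counts, clinical covariates) so every stage can be tested
    against planted ground truth, an exact-enumeration oracle for the
    permutation null on small instances, and an end-to-end pipeline
    driven by a YAML configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    methods,
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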