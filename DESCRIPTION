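Package: emscomp
Title: Elements of Metacommunity Structure with Comparative Trait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies site-by-species incidence matrices into metacommunity
    types from the three elements of metacommunity structure (coherence,
    turnover and boundary clumping) on the first reciprocal-averaging axis,
    tested against fixed-proportional ("r1") and fixed-fixed ("quasiswap")
    permutation null models with standardized effect sizes (Z-scores).
    Partitions multiple-site beta diversity into its Sorensen, Simpson and
    nestedness-resultant components, and provides the cross-metacommunity
    comparative stage: Gower distance and principal coordinates on mixed
    metacommunity traits, Gaussian GLMs, variance inflation factors, linear
    discriminant analysis with greedy Wilks' lambda variable selection,
    MANOVA, and permutation chi-square tests on contingency tables. Includes
    seeded generators for the six canonical metacommunity structures and for
    synthetic trait tables, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    broom,
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
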