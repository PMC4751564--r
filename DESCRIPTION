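Package: ribiscreen
Title: Analysis Pipeline for Genome-Wide Duplex qPCR Reporter Screens of
    Ribosome Biogenesis Gene Repression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing plate-structured duplex qPCR screens of
    stress-dependent reporter gene repression, as used to map TORC1-linked
    growth-control networks in the yeast knock-out collection. Provides
    mixture-model plate normalization of FAM/JOE cycle-threshold data, a
    replicate-derived Gaussian error model with Z-score hit calling, a
    two-stage confirmation design, rapamycin/mock epistasis classification
    of confirmed hits, and permutation tests for protein-interaction
    connectivity of hit sets. A fully parameterised synthetic-screen
    generator reproduces the statistical structure of robot-generated qPCR
    plates so that every stage of the pipeline can be exercised and
    calibrated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
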