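Package: beandiv
Title: Morphological Diversity Analysis of Common Bean Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for phenotypic characterization of
    common bean (Phaseolus vulgaris L.) germplasm collections scored on mixed
    quantitative and coded qualitative trait descriptors. Implements
    Shannon-Weaver diversity indices with half-standard-deviation class
    binning of quantitative traits, coefficients of variation, organ-level and
    collection-level aggregation, UPGMA hierarchical clustering of
    standardized trait matrices, correlation-matrix principal component
    analysis with contribution-rate reporting, and rule-based assignment of
    accession groups to the Andean, Mesoamerican, or introgressed gene pools.
    Ships a synthetic collection generator with two gene-pool archetypes and
    trait-wise introgression so every pipeline stage can be exercised against
    known ground truth.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
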