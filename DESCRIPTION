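Package: slsynergy
Title: Synergy Mapping of Chemotherapy on the Sphingolipid Pathway from
    Single-Cell Fluorescence Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects synergistic and antagonistic chemotherapy-perturbation
    interactions from single-cell fluorescence imaging of cell viability
    (Bliss-style expected versus experimental viability), models single-cell
    phenotypic heterogeneity with Gaussian mixtures selected by MANOVA and
    likelihood criteria, and maps unknown perturbations (chemotherapies,
    autophagy modulators) onto a sphingolipid pathway topology by
    hierarchical clustering of subpopulation heterogeneity profiles. Includes
    a seeded synthetic-data generator for feature panels and multi-channel
    fluorescence fields with full ground truth, a CellProfiler-style
    segmentation and feature-extraction protocol (nuclei from summed
    Hoechst+PI signal, dead-cell flagging by PI, seeded whole-cell growing on
    GFP, intensity/texture/morphology features, puncta counting), and an
    end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
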