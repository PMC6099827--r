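Package: lgflow
Title: Landscape Genetics of Gene Flow: Resistance Surfaces, Circuit
    Theory and Maximum-Likelihood Population-Effects Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A range-wide landscape-genetics pipeline for clustered,
    lek-breeding species: quality control and differentiation statistics
    (Hedrick's GST', GST, Jost's D, individual Bray-Curtis dissimilarity,
    probability of identity) for codominant microsatellite genotypes;
    hierarchical lek clustering with a fixed distance cut; thresholded
    binary habitat/nonhabitat resistance surfaces with a resistance-value
    decorrelation search; a sparse circuit-theory engine for pairwise
    effective resistance and all-to-one current-flow connectivity maps;
    maximum-likelihood population-effects (MLPE) mixed models with
    AIC/AICc model selection and a two-model significance rule; Monte
    Carlo cross-validation of predictive differentiation; and a
    synthetic-data generator producing landscapes, sampling nodes and
    genotypes with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
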