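Package: namGP
Title: Multi-Environment Genomic Prediction for NAM-Style RIL Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for across-environment genomic
    prediction in nested association mapping (NAM) panels of recombinant
    inbred lines. Provides a NAM-like simulator (genetic maps, RIL genotypes
    under the Haldane-Waddington selfed-RIL map function, correlated
    multi-environment phenotypes), genomic relationship matrices, staged
    univariate/bivariate/multivariate EM-REML estimation of across-environment
    genetic and residual covariance, single- and multi-environment RR-BLUP via
    Henderson's mixed-model equations (balanced and unbalanced records),
    composite interval mapping with cofactor selection and permutation LOD
    thresholds, QTL-based prediction, and a CV1/CV2 within-/across-population
    cross-validation engine with covariance-structure comparisons and
    marker-density sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
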