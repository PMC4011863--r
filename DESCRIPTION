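Package: spadefoot
Title: Phylogenetic Comparative Analysis of Developmental Rates, Climate
    and Genome Size
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether species' life-history traits track
    the climates they occupy, built around a case study of spadefoot toads
    and relatives (pelobatoid frogs). Implements maximum-likelihood fitting
    of Brownian motion, Ornstein-Uhlenbeck and Pagel's-lambda models of
    trait evolution with AIC model selection, phylogenetic generalized
    least squares (PGLS) regression under ML-lambda and OU-transformed
    covariance, Pagel's-lambda phylogenetic signal estimation with
    boundary-aware likelihood-ratio tests, reduction of vetted occurrence
    localities to species-level bioclim summaries including the aridity
    index Q = P/((Tmax + Tmin)(Tmax - Tmin)), quantile arithmetic for
    fossil calibration priors (offset lognormal and normal), and a
    synthetic-data generator producing trees, traits and locality tables
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
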