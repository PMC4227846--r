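Package: dissimogram
Title: Distance Decay of Community Similarity and the Degree of Randomness
    in Species Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the degree of randomness in spatially referenced
    ecological communities from the nugget of a fitted dissimilarity-distance
    curve ("dissimogram"). Computes incidence-based Jaccard dissimilarities
    for all plot pairs, fits Gompertz and negative-exponential decay curves by
    Gauss-Newton least squares, and extracts the nugget (dissimilarity at zero
    distance), asymptote, and pseudo-R-squared. Includes management-intensity
    stratification, inter-annual turnover filtering, single- and multi-season
    occupancy-detection models for detectability checks, and a spatially
    explicit metacommunity simulator with a tunable deterministic/random mix
    for validating the randomness estimator against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    minpack.lm,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
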