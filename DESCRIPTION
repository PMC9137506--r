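Package: permbold
Title: Nonparametric Permutation Analysis of Go/NoGo fMRI BOLD Response Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Subject-level general linear model contrast maps for NoGo-versus-Go
    event-related fMRI, voxelwise median group maps, permutation-based
    family-wise error rate thresholds from map-wide maxima/minima with
    volume-filtered cluster extraction, and a singular value decomposition /
    sparse principal component analysis procedure for localizing group
    differences in BOLD response. Includes a synthetic Go/NoGo cohort
    generator with known ground-truth activation so the full pipeline is
    testable end to end, plus summary-statistic two-sample t-tests, Pearson
    correlations and Bonferroni adjustment for cohort tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
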