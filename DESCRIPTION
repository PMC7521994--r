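Package: morphodx
Title: Landmark-Based Facial Shape Analysis and Syndrome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Geometric-morphometric analysis of 3D facial landmark
    configurations for syndrome diagnosis. Provides readers for TPS (LM3)
    and wide-CSV landmark files, generalized Procrustes superimposition,
    object-symmetry decomposition into symmetric and asymmetric shape
    components, robust outlier screening, polynomial age and sex
    standardization, Procrustes MANOVA with ordering-averaged sequential
    sums of squares and residual-randomization permutation tests,
    high-dimensional regularized discriminant analysis (HDRDA) and
    canonical variates analysis (CVA) classifiers with family-aware
    cross-validation and top-k metrics, per-syndrome shape-space
    statistics (severity, distinctiveness, within-syndrome variance,
    integratedness, covariance distance), analyses of unaffected
    relatives, and a synthetic landmark-cohort generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
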