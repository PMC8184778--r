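Package: twaveshape
Title: Geometric Morphometrics of ECG T-Wave Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical shape analysis of the T-wave in lead V5 of the
    electrocardiogram. Provides a synthetic ECG beat and cohort generator
    with analytic landmark ground truth, smoothing-spline estimation of
    first and second derivatives with curvature, derivative-based detection
    of nine T-wave landmarks (including the tangent-method T-end) with
    Bazett rate correction, full generalized Procrustes analysis in the
    planar (complex) representation, Goodall's F test for mean shape
    difference with permutation and bootstrap resampling, thin-plate-spline
    deformation grids, tangent-space shape PCA, JADE independent component
    analysis, per-landmark group comparisons (Welch, Wilcoxon, Yuen,
    Jeffreys-Zellner-Siow Bayes factors) with Hotelling confidence
    ellipses, and exhaustive best-subset logistic discrimination by AIC
    with explicit complete-separation handling.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
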