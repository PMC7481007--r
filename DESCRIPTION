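Package: mdsubspace
Title: Minimally Dependent Activity Subspaces for Working Memory and Motor Preparation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes delay-period neural population activity into two
    minimally dependent low-dimensional subspaces (working memory and motor
    preparation) by minimizing histogram-based mutual information over a 2x2
    mixing model. Includes cross-temporal population decoding with linear
    discriminant analysis, subspace geometry (principal angles, loading
    weights, inter-to-intra cluster distance ratios, effective
    dimensionality), bootstrap and shuffle statistics with Hedges' g effect
    sizes, ANOVA-based selectivity classification, and two divisive-
    normalization network simulators (a ring bump attractor and a linear
    subspace model) that generate synthetic population recordings with the
    assumed structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
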