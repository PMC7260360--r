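Package: spatsupp
Title: Spatial Suppression Modelling and Simulation for Visual Motion
    Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a divisive-normalization model of visual spatial
    suppression with a top-down (attentional) gain field, and the analysis
    pipeline used to study weaker suppression in autism spectrum disorder:
    prediction of motion duration thresholds from the model, simulation of
    the adaptive (Psi) staircase duration-threshold task with Weibull
    psychometric fitting and exclusion rules, an fMRI percent-signal-change
    suppression metric for block-design ROI time series, the accompanying
    statistical procedures (chi-square with Yates correction, pooled t tests,
    a two-stage group-by-size test, permutation-based Pearson correlations,
    Bonferroni adjustment), and synthetic-cohort generators with known ground
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
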