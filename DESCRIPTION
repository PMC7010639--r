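Package: evreg
Title: Event-Related Regression Analysis of Decision Evidence in Neural Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating how strongly neural time series follow
    within-trial fluctuations of perceptual decision evidence. Implements a
    random-dot evidence task generator (2D-Gaussian dot sequences with
    fifth-dot variants, mirroring and catch trials), an ideal-observer
    definition of momentary and accumulated evidence with a bounded-accumulator
    behavioral simulator, a ground-truth signal simulator for
    multi-participant sensor tensors, three event-aligned regression designs
    (per-trial standard, overlapping-epoch expanded, and response-aligned)
    with a z-scoring contract that makes coefficients approximate
    correlations, second-level t-tests with Benjamini-Hochberg false
    discovery rate control over time-by-location grids, permutation
    baselines, and a spatial correlation-pattern window-difference test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
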