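Package: cccm
Title: Causalized Convergent Cross Mapping for Time Series Causality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects linear and nonlinear causal coupling between time series
    with convergent cross mapping (CCM) and its causalized variant (cCCM), in
    which the nearest-neighbor search on the delay-embedded shadow manifold is
    restricted to strictly earlier time indices so that the present is never
    reconstructed from the future. Includes multivariate conditional cCCM via
    a cross-map causality ratio over joint shadow manifolds, ordinary
    least-squares Granger causality for side-by-side comparison, the
    closed-form link between cross-map skill and average directed information,
    seeded generators for a suite of benchmark systems (coupled logistic maps,
    autoregressive pairs, tone-in-noise processes, finite-impulse-response
    systems with memory, confounded trios), SNR-calibrated noise injection,
    spline upsampling, and a pairwise/conditional network pipeline over CSV
    input with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
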