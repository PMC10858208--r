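Package: doct
Title: Dynamic Optical Coherence Tomography Analysis of Tumor Spheroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic optical coherence tomography (D-OCT) analysis of
    tumor spheroids. Computes the two standard dynamics contrasts from repeated
    B-scan time series - logarithmic intensity variance (LIV, the temporal
    variance of the dB-scaled OCT signal) and the late OCT correlation decay
    speed (OCDS_l, the slope of the temporal autocorrelation over a late delay
    window) - renders the usual hue/value pseudo-color composites, segments
    spheroid tissue from mean-intensity volumes, and quantifies volume, mean
    dynamics and dead-cell ratios across a drug-treatment study with Welch
    t-test group comparisons. Includes a synthetic dynamic-speckle spheroid
    phantom (Ornstein-Uhlenbeck field model with known motility fraction and
    decorrelation time, plus closed-form Siegert correlation oracles) so the
    whole pipeline can be exercised end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
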