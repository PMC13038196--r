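Package: cometkin
Title: Microtubule Plus-End Comet Tracking, Kinematics and Signal Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, detection, linking and kinematic analysis of EB1
    plus-end comets in live-cell fluorescence movies. Provides a synthetic
    movie generator with known ground truth for unidirectional (radial) and
    bidirectional (bundled) microtubule growth regimes, Hessian tubeness
    ridge enhancement with subpixel comet localization, frame-to-frame
    linear-assignment (LAP) track linking with optional gap closing,
    calibrated per-track statistics (velocity, movement angle,
    directionality concentration, angle fluctuation, track straightness),
    wide-polyline kymograph reslicing, a normality-gated two-group and
    multi-group comparison protocol, and a percentile-based ChIP signal
    enrichment filter over bedGraph tracks and BED gene regions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    tiff,
    mgcv,
    stats,
    tools,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
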