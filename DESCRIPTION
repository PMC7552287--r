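Package: cladocardio
Title: Cardiovascular Videography Analysis for Water Fleas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-speed-videography cardiovascular analysis for cladocerans
    (Daphnia, Moina) and similar transparent invertebrates. Extracts heartbeat
    signals from heart-ROI pixel-intensity dynamics, detects beats with
    sub-frame timing, and quantifies rhythm regularity with Poincare
    descriptors and short-time Fourier spectrograms. Tracks hemocytes via
    scale-normalised Laplacian-of-Gaussian spot detection and optimal
    frame-to-frame assignment to estimate blood-flow velocity. Computes
    cardiac geometry endpoints (fractional shortening, end-diastolic and
    end-systolic volumes, stroke volume, ejection fraction, cardiac output)
    from diastolic and systolic heart diameters under a prolate-ellipsoid
    chamber model. Includes ground-truthed synthetic beating-heart and
    pulsatile-flow video generators for validation, and descriptive group
    summaries with rank-based comparisons for exposure experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    tiff,
    clue,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    signal,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
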