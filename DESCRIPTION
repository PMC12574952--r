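Package: painvar
Title: Neural Variability Analysis of Pain Intensity Discriminability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed neural-variability analysis of epoched single-channel
    EEG and its association with perceived-intensity discriminability.
    Provides temporal standard deviation and permutation entropy sliding
    tracks, signal-detection discriminability scores from 0-10 ratings,
    point-by-point (partial) correlation inference with Benjamini-Hochberg
    correction and Jeffreys-Zellner-Siow Bayes factors, two-predictor
    dominance decomposition, baseline-sampled noise-injection simulations,
    bootstrap power maps over subjects and trials, cross-modality rating
    matching, band-limited oscillatory profiling, and a synthetic
    multi-subject cohort generator with planted effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
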