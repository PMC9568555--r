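Package: metfref
Title: Reference Ranges and Validation for Middle Ear Transfer Functions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and application of statistical reference ranges
    (two-sided normal tolerance intervals) for middle ear transfer functions
    (METFs) measured with laser Doppler vibrometry on temporal bone specimens.
    Covers the full pipeline: H1 transfer-function estimation from two-channel
    voltage recordings with coherence and adjacent-bin SNR quality gating,
    linear interpolation onto the audiological frequency grid, Tukey-fence
    outlier screening with discard/truncate exclusion rules, Welch t-test group
    comparisons with Holm adjustment, crossed random-effects variance
    decomposition with Nakagawa-Schielzeth R-squared, per-frequency tolerance
    interval reference tables, and a validation protocol for new measurements.
    Includes a seeded synthetic METF population generator with crossed random
    intercepts for specimen, measurement method and research group.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
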