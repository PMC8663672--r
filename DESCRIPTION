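Package: biocue
Title: Biocueing Engine for Wearable Heart-Rate Arousal Feedback
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A device-independent biocueing engine for wrist-worn heart-rate
    data. Calibrates a personal heart-rate baseline (mean and standard
    deviation over a fixed number of reliable, cadence-spaced samples),
    quantizes incoming beats-per-minute readings into discrete arousal
    levels from -3 to 5 in 1-SD bands, emits vibration and message cues
    under an activity-aware gating policy, maintains an annotatable event
    timeline, computes a corrected usage (adherence) metric that excludes
    implausibly low heart rates and nighttime samples, and scores common
    self-report evaluation instruments (System Usability Scale and Likert
    scales) with exact Wilcoxon matched-pairs statistics. Includes a seeded
    simulator of wearable heart-rate scenarios with ground truth for
    end-to-end evaluation of cue sensitivity and false-alert rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
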