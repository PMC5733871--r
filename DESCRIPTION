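Package: iqsa
Title: Quaternion-Based EEG Feature Extraction and Boosted Tree
    Classification for Motor Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-domain analysis of multichannel EEG for motor-imagery
    brain-computer interfaces. Four EEG channels are embedded in a
    quaternion stream, rotated against a time-displaced copy of
    themselves, and the modulus of the rotated stream is summarised over
    superposed (overlapping) sliding windows by four statistical
    features: mean, variance, contrast and homogeneity. Window features
    feed a boosting ensemble of CART decision trees with
    validation-derived reliability weights and weighted majority voting.
    Includes per-class sensitivity/specificity evaluation, the Friedman
    aligned-ranks procedure for comparing algorithms across subjects, a
    seeded generator of cue-paradigm EEG-like sessions for testing, CSV
    input/output and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
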