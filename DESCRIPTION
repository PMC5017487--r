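Package: aaei
Title: Accumulated Activity Effective Index and Fuzzy-Logic Exercise Prompting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for managing physical activity from wrist/arm-worn tri-axial
    accelerometry. Implements the full pipeline from raw 40 Hz acceleration to
    daily prompting decisions: gravity/motion separation with a second-order
    elliptic low-pass filter, two-second windowing, time- and frequency-domain
    feature extraction, decision-tree activity-level classification on the MET
    scale, the Accumulated Activity Effective Index (AAEI) day-resolution
    recursion with its adaptive decay threshold, a Mamdani (min-max) fuzzy-logic
    prompt decision engine with centre-of-area defuzzification and a
    MET-minute prompting value, and a closed-loop Poisson exercise simulator in
    which delivered prompts replace the day's activity for a compliant user.
    A synthetic accelerometer-signal generator makes the recognition pipeline
    trainable and testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    rpart,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
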