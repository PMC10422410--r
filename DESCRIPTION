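Package: etmt
Title: Eye-Tracking Trail-Making Test Scoring for Cognitive Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores eye-tracking recordings of the Trail-Making Test (TMT)
    for cognitive-impairment screening. Detects fixations from raw 60 Hz
    gaze logs with a dispersion-threshold (I-DT) algorithm, extracts
    thirteen fixation-based features across low (fixation statistics),
    middle (per-target dwell, glances, revisits), and high (scanpath
    Levenshtein score, completion time, error rate, inattentional
    blindness) levels, and combines them into three scores: a
    visual-search-speed score and a focused-attention score from two
    Mamdani fuzzy-inference systems, and an overall cognitive-impairment
    score from a k-means-labeled Takagi-Sugeno ANFIS trained by hybrid
    least-squares and gradient learning. Includes a synthetic TMT-session
    simulator with controllable impairment behaviour so the full pipeline
    can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
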