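Package: mcdtkit
Title: Sensorized Motor-Cognitive Dual-Task Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of sensorized motor-and-cognitive dual-task
    (MCDT) protocols for cognitive-impairment screening. Takes raw wearable
    inertial recordings of finger/foot tapping and 10-meter walking performed
    under serial-subtraction cognitive loads, low-pass filters and segments
    them into movement cycles, extracts kinematic features, computes standard
    and cognitively weighted dual-task costs, reduces each exercise to a
    pooled composite index by correlation/effect-size screening, and
    classifies diagnostic groups (cognitively healthy older adults,
    subjective cognitive impairment, mild cognitive impairment) with
    leave-one-out cross-validated logistic models. Includes a seeded
    synthetic cohort and signal generator so the full pipeline is runnable
    and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    nnet,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
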