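Package: fmriseq
Title: Detecting Sub-Second Neural Event Sequences in fMRI Decoding Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for detecting fast sequential neural events from slowly
    sampled probabilistic pattern-classifier time courses. Implements a
    flattened single-cycle sine model of the multivariate decoding response,
    its constrained least-squares fit, closed-form predictions for overlapping
    event sequences (difference waveform, predicted difference-wave frequency,
    speed-adjusted forward/backward periods), TR-wise sequentiality statistics
    (regression slope, Kendall rank correlation, mean step size, decoded
    position and transitions), interference metrics for two-item repetition
    trials, and a Lomb-Scargle frequency-spectrum detector that distinguishes
    sub-second from supra-second sequences in resting-state data. Includes a
    synthetic-data generator reproducing the counterbalanced trial schedules
    and a one-vs-rest probabilistic decoding stage, so the full pipeline can
    be exercised end to end without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
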