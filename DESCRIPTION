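Package: rhythmscan
Title: Rhythmicity Detection and Differential Cycling in Replicated
    Expression Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects 24-hour cycling of transcripts in short, replicated
    expression time courses by combining a rank-based test against
    time-shifted cosine references (JTK_CYCLE, with a tie-aware exact
    permutation null) and the Lomb-Scargle periodogram at a fixed target
    period, integrating the two p-values with Fisher's method.  Estimates
    per-transcript baseline expression (bEXP), relative amplitude (rAMP)
    and peak phase, and classifies genotype-specific loss of cycling
    between paired conditions (e.g. wild type versus knockout).  Includes
    a synthetic-data generator that emulates the sampling designs of
    circadian tissue-collection experiments for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
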