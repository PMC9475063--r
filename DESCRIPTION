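Package: avcapture
Title: Visual Capture of Sound-Source Distance: Simulation and
    Probabilistic Coincidence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying audio-visual capture (the ventriloquist
    effect) in the distance dimension. Simulates yes/no coincidence
    judgments and absolute distance judgments from a correlated
    log-normal observer model, computes the empirical discriminability
    statistic d' = z(pc_max) - z(pc) with subject-level bootstrap
    confidence intervals, fits power-law distance-perception functions,
    predicts coincidence discriminability under three probabilistic
    models (linear scale with constant variance, linear scale with
    distance-scaled variance, and logarithmic scale / log-normal), fits
    those models to d' curves by bound-constrained nonlinear least
    squares, and summarizes model comparison by RMS error. Also fits
    dB-per-doubling functions to acoustic distance cues (level and
    direct-to-reverberant ratio) and computes the critical distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
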