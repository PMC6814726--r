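Package: sqmwin
Title: Discrete Time-Window Model of Feature Integration in the
    Sequential Metacontrast Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for temporal feature
    integration in the sequential metacontrast paradigm (SQM). Builds
    SQM stimulus sequences (a central vernier followed by streams of
    flanking lines), runs a two-stage perceptual model in which
    per-location leaky-integrator memory boxes buffer offset evidence
    that is summed at the end of discrete integration windows and fed
    to a reduced two-variable attractor decision network, and estimates
    vernier dominance by Monte-Carlo simulation. Also provides the
    accompanying psychophysics statistics (dominance summaries, paired
    t tests with Holm correction and noncentral-t confidence intervals
    for Cohen's d, power and sample-size computation) and a synthetic
    observer-cohort generator for end-to-end testing without human
    data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
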