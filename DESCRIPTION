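Package: duetsync
Title: Dyadic Sensorimotor Synchronization Analysis for Piano Duets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of interpersonal keystroke timing in
    piano duet performance. Provides a coupled linear phase-correction
    timekeeper simulator for two-player phrase performance with cued tempo
    changes, keystroke event table input/output (CSV and Standard MIDI
    Files), a three-stage behavioral trial quality-control pipeline
    (wrong notes, tempo goodness of fit, inter-keystroke-interval outlier
    trimming), synchronization accuracy/stability and lagged
    cross-correlation adaptation metrics, fully-within repeated-measures
    ANOVA for two-level factorial designs with partial eta squared, paired
    t tests with Cohen's d, Pearson correlation and Fisher r-to-z
    comparison of two correlations, and a nonparametric Monte Carlo
    simulation of cluster-extent thresholds for smoothed Gaussian noise
    volumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
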