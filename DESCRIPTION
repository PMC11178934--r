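Package: drosleep
Title: Sleep Staging, Circadian Rhythmicity and Homeostasis Analysis for
    Drosophila Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the behavioral analysis of Drosophila sleep from
    ethoscope-style activity recordings: a closed-loop simulator of
    circadian-modulated four-state behavior with sleep-pressure dynamics and
    stimulus protocols (baseline, mechanical and social sleep deprivation,
    air-puff arousal probing); sleep scoring by the five-minute immobility
    rule with quality-control exclusions; constrained four-state hidden
    Markov model sleep staging (Baum-Welch fitting, Viterbi decoding, stage
    bout analysis); chi-square periodogram analysis of circadian rhythmicity
    in constant darkness; and homeostasis statistics including exact Wilcoxon
    rank-sum tests, Benjamini-Hochberg false discovery rate adjustment,
    bootstrapped time-course confidence intervals, sleep-pressure trend tests
    and log-rank survival comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
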