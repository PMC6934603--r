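Package: swingtime
Title: Microtiming Analysis and Manipulation of Swung MIDI Performances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and manipulates the microtiming deviations (MTDs) of
    swung-eighth-note MIDI performances recorded against a metronome. Notes are
    classified on an eighth-note-triplet grid (960 ticks per quarter note) into
    base, swing and disregarded middle-triplet classes; per-note deviations are
    measured about the recording's mean base and swing positions, summarised as
    millisecond spreads, an average swing ratio with its variability, and serial
    Spearman rank correlations between neighbouring base/swing deviations.
    Deviations can be scaled multiplicatively (quantized, exaggerated, inverted)
    while leaving dynamics, durations and sustain-pedal data untouched. Includes
    a Standard MIDI File reader/writer on a canonical 960-tick timeline, a
    synthetic performance generator with controlled timing statistics (i.i.d.,
    AR(1) or power-law correlated noise), and ROC/AUC comparison of ordinal
    listener ratings with DeLong confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
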