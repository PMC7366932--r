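Package: swdscope
Title: Detection and State-Dependent Analysis of Spike-Wave Discharges in Mouse Video-EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying nonconvulsive spike-wave
    discharges (SWDs) in rodent video-EEG recordings. Behavioral states
    (sleep, waking immobility, movement, mixed) are staged from video
    tracking trajectories alone; SWD candidates are detected by 7-23 Hz
    band-pass filtering and Hilbert-envelope thresholding, screened by a
    duration/cycle-count inclusion rule, and normalized by artifact-free
    hours spent in each behavioral state. Spectral summaries (Welch power
    spectral density of merged discharges, absolute and relative state PSDs)
    and group-level inference (repeated-measures ANOVA with
    Greenhouse-Geisser correction followed by FDR-corrected paired t-tests
    against a control session) complete the analysis. A synthetic-session
    generator with known ground truth makes every stage testable without
    animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
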