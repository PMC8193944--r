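Package: synphys
Title: Quantal, Synaptic-Event, Dose-Response and Circadian Entrainment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for synaptic physiology and circadian behaviour in
    aging studies: quantal-content estimation by the method of failures under a
    Poisson release model, detection and summary statistics of spontaneous
    inhibitory postsynaptic currents, Hill concentration-response fitting,
    ratiometric (fura-2) calcium-transient quantification, wheel-running
    entrainment metrics (10%-of-peak activity onsets, least-squares phase angle,
    day-to-day onset variability, total daily activity), and a two-way ANOVA
    computable from per-group summary statistics. A synthetic-data generator
    produces current traces, evoked-trial sets, ratio traces and actograms with
    known ground truth so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
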