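Package: seizstage
Title: Quantitative Video-EEG Staging of Kainate-Induced Status Epilepticus
Version: 0.1.0
Authors@R: person("Seizstage", "Developers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of single-channel rodent EEG
    during chemoconvulsant-induced status epilepticus. Generates ground-truth
    labeled synthetic EEG with stage-specific epileptiform spike morphology,
    band-limited background power and telemetry activity counts; extracts
    per-spike (amplitude, duration, inter-spike interval, rate) and per-10-s
    epoch band-power features (delta through gamma); classifies epochs into
    modified Racine stages, high-frequency trigger (HFT) runs and artifact
    classes with an explicit published rule table; scores behavioral seizure
    severity over the 2-h status epilepticus window; and simulates repeated
    low dose versus single high dose kainate cohorts with the associated
    summary statistics (binary-coded t-tests, two-way ANOVA on spike rates,
    mortality / stage-5 attainment / animal wastage arithmetic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
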