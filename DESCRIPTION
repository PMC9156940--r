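Package: nremlink
Title: Linking NREM Sleep Neural Activity to Next-Day Exploratory Behavior
Version: 0.1.0
Authors@R:
    person("Maze", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for experiments that relate
    midbrain population activity recorded by fiber photometry during sleep to
    exploratory behavior in a Barnes-style escape maze on the following day.
    Provides EEG/EMG vigilance-state scoring in fixed epochs, delta-F-over-F
    normalization and prominence-based calcium-transient detection with
    per-state activity summaries, trajectory-derived maze statistics
    (port-zone visits, visit-speed mixtures, escape metrics, novelty
    preference), a temporally regularized variational-autoencoder plus
    self-organizing-map behavioral clustering stage, the sleep-to-behavior
    correlation layer, and a ground-truth-labeled multimodal synthetic-data
    generator used to validate every stage.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
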