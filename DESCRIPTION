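Package: hpcnac
Title: Ensemble Electrophysiology Analysis for Hippocampus-Accumbens Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and cross-session tracking of neuronal co-activation
    assemblies from sorted spike trains (25-ms binning, Marcenko-Pastur
    pattern counting, ICA pattern extraction, projector-based activation
    strength), waveform-based classification of striatal units into
    fast-spiking interneurons, medium spiny neurons and tonically active
    neurons, oscillation-controlled cross-region spike-timing analysis with
    theta-phase-preserving shift surrogates, ensemble-to-ensemble GLM spike
    count prediction in theta-cycle bins, and place-preference behavioral
    scoring. Ships a synthetic-session generator with ground truth so every
    stage of the chain can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ica,
    clue,
    signal,
    cluster,
    mclust,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
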