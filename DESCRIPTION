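Package: erspconn
Title: Event-Related Spectral Perturbation and Imaginary-Coherence
    Connectivity for Oscillatory EEG
Version: 0.1.0
Authors@R:
    person("Signal", "Methods Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for event-related oscillatory EEG: BrainVision
    reading, detrending and linked-mastoid re-referencing, zero-phase FIR
    band-pass filtering, stimulus-locked epoching with frontal amplitude
    rejection and infomax ICA artifact removal; event-related spectral
    perturbation (ERSP) maps with band-by-window summaries; seed-based
    functional connectivity via multitaper cross-spectra, corrected imaginary
    coherence (ciCOH) and its event-related baseline contrast (ER-ciCOH);
    and cluster-based non-parametric permutation statistics with
    max-statistic family-wise error control. Includes a fully parameterised
    synthetic EEG generator with a ground-truth effect ledger for validating
    every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
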