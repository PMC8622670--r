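Package: bulbdyn
Title: Olfactory Bulb Network Dynamics from LFP and Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for olfactory-bulb network dynamics in
    freely behaving and anesthetized mice: behavior-state-conditioned
    spectral analysis of local field potentials (theta, beta, and gamma
    band power via Welch's method), detection and quantification of
    spontaneous calcium events in mitral/tufted cell ROI traces with a
    field-of-view-referenced threshold, kernel-regression quantification
    of odor-evoked responses using GCaMP6s impulse-response regressors,
    distance-resolved pairwise correlation profiles, Ward hierarchical
    clustering of field-of-view activity vectors, and scoring of the
    habituation-dishabituation olfactory task. Includes a synthetic-data
    generator with known ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    signal,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
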