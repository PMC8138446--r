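Package: mpsddi
Title: Liver-Heart Microphysiological System Modelling and Drug-Drug
    Interaction Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for an integrated liver-heart
    microphysiological system (MPS, "organ-on-a-chip"). Provides a
    two-dimensional finite-volume solver for oxygen and small-molecule
    transport in a membrane-bilayer liver chip (advection-diffusion with
    Michaelis-Menten cellular uptake and gas exchange through the PDMS
    body), per-beat optical action-potential metrics for cardiac MPS
    recordings (APD30/80/90, Fridericia rate correction, triangulation),
    exhaustive-search block-matching optical flow for contraction videos,
    Hill-equation dose-response fitting, correction of nominal drug doses
    for absorption into PDMS, a well-mixed liver metabolism stage with
    competitive CYP3A4 inhibition, and an in-silico functional-coupling
    pipeline that propagates a drug dose through the liver stage into a
    predicted cardiac repolarization response. Synthetic-data generators
    with known ground truth stand in for all wet-lab inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
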