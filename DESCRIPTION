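Package: sksense
Title: SK Current Isolation, Submembrane Calcium Reconstruction and
    Ca2+-Sensitivity Analysis for Cardiac Myocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing small-conductance Ca2+-activated K+ (SK)
    currents recorded from ventricular myocytes under whole-cell voltage
    clamp with simultaneous confocal Ca2+ imaging. Converts single-wavelength
    indicator fluorescence to intracellular calcium, reconstructs submembrane
    calcium from the bulk transient via a diffusion-constant derivative term,
    isolates the blocker (apamin / UCL-1684)-sensitive current by trace
    subtraction, builds current-voltage and peak-calcium summaries, estimates
    in-situ Hill Ca2+ sensitivity from calcium-transient decay ramps, and
    computes optical-mapping repolarization metrics (activation time, APD
    maps, conduction velocity). A mechanistic simulator of biphasic
    (activation + voltage-dependent inhibition) SK gating generates fully
    specified synthetic experiments, including the PKA/phosphorylation relief
    of rectification, so that every analysis stage can be validated against
    known ground truth. Includes a mass-action free-ion solver for pipette
    solution recipes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
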