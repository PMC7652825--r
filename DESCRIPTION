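Package: habqsm
Title: Quantitative Susceptibility Mapping and ROI Statistics for the Human Habenula
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative susceptibility
    mapping (QSM) of the habenula from multi-echo gradient-echo MRI. Provides a
    digital phantom with iron/myelin-driven susceptibility and R2* ground truth,
    a reconstruction chain (coil combination, Laplacian phase unwrapping,
    V-SHARP background-field removal, dipole inversion, Rician-corrected R2*
    fitting), ROI machinery (minimum-vein slice selection, posterior edge
    adjustment, outer ROI, peak-cluster growing, CSF referencing), and the
    statistics layer (four contrast-to-noise ratios, susceptibility-R2*
    correlation, intraclass correlation for raters, representative-scan
    selection, group summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
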