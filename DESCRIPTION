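Package: dcmflow
Title: Wall Kinematics, Rheology and Particle-Tracking Analysis for a
    Dynamic Colon Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative toolkit for biorelevant colonic-motility
    experiments in a ten-unit dynamic colon model (DCM). Implements
    Herschel-Bulkley rheology with particle relaxation times and Reynolds
    numbers; the programmed contraction-hold-relaxation wall-motion
    protocol and the segment-based colonic motility index; detection and
    linking of haustral contraction events in cine-MRI-derived time
    series; Savitzky-Golay smoothing, pass segmentation, propulsive
    displacement detection and residence-time accounting for Lagrangian
    particle tracks; and seeded generators for synthetic wall-driven
    flow, particle tracks, compartmental tracer mixing and haustral
    series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
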