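Package: nanobarcoder
Title: Simulation, Localization and Machine-Learning Classification of
    Fluorescently Barcoded Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to write, read and classify fluorescent nanoparticle
    barcodes at the single-particle level. Provides a forward optical model
    and synthetic confocal image generator for dye-loaded sub-diffraction
    particles (size and encapsulation heterogeneity, aggregation-caused
    quenching, FRET, cross-excitation, emission bleed-through, shot and
    camera noise); a spot-detection and 2-D Gaussian fitting reader that
    assembles per-particle multi-channel optical fingerprints; a multi-model
    barcode classifier with stratified cross-validation, tuning and
    evaluation; and analysis routines for backward class elimination,
    Y-scrambling, feature importance and ablation, learning curves, PCA
    fingerprint visualization and virtual-mixture scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    class,
    e1071,
    nnet,
    ranger,
    rpart,
    xgboost,
    minpack.lm,
    tiff,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
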