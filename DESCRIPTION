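Package: plastidyn
Title: Light-Driven Chloroplast Morphodynamics in Dinoflagellates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models and measures the light-avoidance contraction of the
    reticulated chloroplast of the dinoflagellate Pyrocystis lunula. Provides
    a two-sensor viscoelastic (Kelvin-Voigt) light-response model with forward
    simulation, closed-form constant-light solutions, low-pass filter analysis
    and least-squares parameter fitting; a brightfield pipeline for projected
    chloroplast area and relative light-loss traces; a confocal pipeline for
    depth-attenuation correction, segmentation and binary-mask topology; 3D
    skeleton-to-graph extraction with node coarse-graining and network metrics;
    velocity-predictive node tracking with Savitzky-Golay velocities, mean
    squared displacement and speed-distance (strain-rate) analysis; and a
    seeded synthetic-data generator (cell geometry, reticulum graphs, affine
    contraction kinematics, rendered confocal and brightfield series) that
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
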