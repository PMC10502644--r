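Package: fluidmre
Title: Tissue Fluidity and Stiffness Analysis for Magnetic Resonance
    Elastography
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing viscoelastic measurements of soft
    tissues and tissue-mimicking gels obtained with magnetic resonance
    elastography (MRE). Implements the complex shear modulus algebra
    (phase angle, normalised fluidity, shear-wave speed conversion),
    two-parameter springpot (fractional element) model fitting of
    dispersion data, Bessel-profile fitting of axial shear waves in
    cylindrical tabletop MRE samples, a desk-scale multifrequency
    Helmholtz wave-field simulator with MDEV-style magnitude inversion,
    fluidity-map features (regime labelling, spatial heterogeneity,
    tumour-front texture, Saffman-Taylor interfacial stability), a
    biomechanical tumour growth-pattern classification scheme with
    packaged meta-analysis fixtures, and displacement analysis of 3D
    cell trajectories with a one-cell-radius unjamming threshold.
    Seeded synthetic generators produce every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
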