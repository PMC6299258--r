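Package: neodwi
Title: Neonatal Diffusion MRI Processing, Microstructure Modelling and
    Tractography at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An artefact-aware processing toolkit for neonatal multi-shell
    diffusion MRI. Provides reversed-phase-encode susceptibility field
    estimation and unwarping, rigid volume realignment with b-vector
    rotation, spherical-harmonic outlier slice detection and replacement,
    super-resolution of thick overlapping slices, diffusion kurtosis and
    NODDI-Bingham microstructure fitting, spherical deconvolution with
    voxel-wise tensor kernels and automatic relevance determination,
    protocol-driven probabilistic tractography, and a quality-control
    report generator. A synthetic neonatal phantom module generates
    multi-shell data with known ground truth and scanner-realistic
    artefacts so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
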