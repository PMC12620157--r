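Package: slabkq
Title: Accelerated 3D Multi-Slab Diffusion MRI Simulation, Joint k-q
    Reconstruction and Microstructure Fitting
Version: 0.1.0
Authors@R:
    person("slabkq", "developers", email = "slabkq@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and reconstruct accelerated 3D multi-slab
    diffusion-weighted MRI acquisitions. Provides multi-shell acquisition
    protocols with B-tensor encoding shapes and randomized 2D-CAIPI ky-kz
    undersampling masks; a three-compartment (intra-axonal stick,
    extra-axonal zeppelin, free water) diffusion signal model with
    orientation-distribution convolution and closed-form powder averages;
    a digital multi-coil head phantom producing per-shot motion phases,
    undersampled multi-channel k-space and 2D navigators; a compact fully
    connected denoising autoencoder acting as a plug-and-play q-space
    prior; phase-compensated SENSE operators, CG-SENSE navigator phase
    estimation and a TV- plus autoencoder-regularized joint k-q
    reconstruction; and compartment-model, DTI and DKI fitting with ROI
    statistics. Includes a minimal NIfTI-1 reader/writer and FSL-style
    bval/bvec gradient-table I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
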