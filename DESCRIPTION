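Package: naquant
Title: Quantitative Sodium MRI Simulation, Reconstruction and Calibration
Version: 0.1.0
Authors@R: person("naquant", "developers", email = "naquant@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification pipeline for sodium (23Na) MRI
    with external reference-vial calibration. Provides digital phantoms with
    known sodium concentration, synthetic transmit/receive coil fields,
    golden-angle density-adapted 3D radial (DA-3DPR) trajectories with
    density compensation, a multi-channel FLASH steady-state k-space
    simulator, Kaiser-Bessel gridding (NUFFT) reconstruction with radial
    apodization and zerofilling, dual-flip-angle B1+ mapping, the
    T1/B1+/B1- correction chain, linear-regression concentration
    calibration against reference vials, and evaluation tools (VOI
    statistics, Scott's-rule histograms with Gaussian-fit FWHM, simulated
    point-spread functions and effective resolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    tools,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
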