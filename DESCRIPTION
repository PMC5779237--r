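Package: sptnano
Title: Single-Particle Tracking Analysis of Receptor Confinement in Synaptic Nanodomains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for three-dimensional single-particle tracking of
    membrane receptors imaged with astigmatism-based super-resolution microscopy.
    Simulates two-population receptor trajectory mixtures, PALM localization
    clusters marking post-synaptic densities, fiducial drift traces, and
    two-channel nanohole calibration grids; localizes astigmatic spots and
    converts width asymmetry to axial position; corrects stage drift and
    chromatic aberration; links localizations into trajectories with a
    displacement gate; computes mean-squared-displacement diffusion
    coefficients and trajectory ranges; deconvolves mobility histograms into
    Gaussian components; and classifies trajectories as synaptic from their
    distance to clustered PSD markers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    mclust,
    tiff
Config/testthat/edition: 3
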