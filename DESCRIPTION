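Package: gpmembrane
Title: Generalized Polarization Imaging and Membrane Probe Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for environment-sensitive membrane dyes
    (di-4-ANEPPDHQ, Laurdan, di-8-ANEPPS): generalized polarization (GP)
    from emission spectra and from two-channel fluorescence images,
    manually seeded watershed segmentation with per-cell plasma-membrane
    pixel extraction and median GP, treatment-level statistics (one-way
    ANOVA with Tukey HSD, Deming errors-in-variables regression for
    cross-dye comparison), and post-processing of lipid-bilayer
    trajectories (phosphate-plane thickness, dye tilt angle, heavy-atom
    RMSD, chromophore depth below the membrane-water interface, window
    averages, and two-start convergence). A synthetic-data module
    generates images, spectra and bilayer-like trajectories with recorded
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
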