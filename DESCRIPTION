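Package: retfield
Title: Field-Cable Modelling of Epiretinal Prosthesis Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates per-electrode retinal ganglion cell activation
    thresholds and phosphene-size predictions for epiretinal prostheses.
    Provides a synthetic virtual-patient geometry generator (electrode-retina
    distance, retinal thickness, fibrotic tissue), a finite-volume voxel
    solver for the quasi-static volume-conductor problem with tissue
    conductivities and a retinal pigment epithelium contact impedance,
    Jansonius-type nerve-fiber-layer axon trajectories, centroidal-Voronoi
    soma placement, Fohlmeister-Miller-type multi-compartment cable models of
    retinal ganglion cells with bisection threshold search, convex-hull
    activation-area analysis versus stimulus amplitude, and electrode-level
    regression models of perceptual threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
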