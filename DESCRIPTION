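Package: dvioct
Title: Deformation Velocity Imaging for Phase-Sensitive Fourier-Domain OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tomographic imaging of nanometre-per-second relative axial
    velocities inside deforming semi-solid samples from the Fourier phase of
    complex optical coherence tomography (OCT) B-scan stacks. Provides a
    synthetic speckle phantom generator with exact deformation ground truth,
    iterative graph-search (dynamic programming) segmentation of corneal and
    container interfaces, deformation-velocity image computation with
    bulk-motion removal by per-column phase referencing, automated corneal
    thickness time series, and a one-dimensional Darcy-flow osmotic
    de-swelling model of the corneal stroma with deterministic fitting of its
    transport constants to measured velocity-depth profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
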