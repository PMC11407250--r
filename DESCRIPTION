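Package: fetalnirs
Title: Simulation-Based Sensitivity Analysis for Transabdominal Fetal Pulse Oximetry
Version: 0.1.0
Authors@R: person("fetalnirs", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study whether near-infrared light launched on the
    maternal abdomen can sense the fetal brain. Generates layered synthetic
    maternal-fetal tetrahedral phantoms with an embedded fetal head, computes
    wavelength-dependent tissue absorption and scattering from hemoglobin,
    water and fat content, solves the continuous-wave diffusion equation with
    linear finite elements, derives adjoint absorption Jacobians and
    flat-field imaging sensitivity with spatially variant regularization, and
    evaluates pulsatile optical-density changes, detector dynamic range and a
    distance-dependent measurement noise model over configurable
    source-detector grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
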