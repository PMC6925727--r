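Package: canalssd
Title: Steklov Spectrum Shape Evaluation of Root Canal Preparations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Boundary-element computation of the Steklov (Dirichlet-to-Neumann)
    spectrum of closed triangle meshes, automatic construction of an ideal
    benchmark root canal by key-section selection and lofting, and a
    Gaussian-curvature-weighted spectral shape distance (SSD) between a
    prepared canal and its ideal, alongside the legacy slice-based
    volume/area/transportation metrics.  Includes deterministic synthetic
    canal and analytic fixture generators, mesh I/O for OFF/PLY/STL/OBJ,
    and a command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
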