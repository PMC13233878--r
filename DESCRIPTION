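Package: biaxfit
Title: Inverse Identification of Anisotropic Hyperelastic Parameters from
    Planar Biaxial Rake Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing soft airway tissue from planar
    equi-biaxial tensile tests on rake-mounted samples. Implements the
    Holzapfel-Gasser-Ogden (HGO) anisotropic hyperelastic model under
    incompressible plane stress, an analytic homogeneous-deformation
    forward model and a quarter-symmetry total-Lagrangian membrane finite
    element model of the rake test, Latin hypercube sampling of the
    material parameter space, a feedforward neural-network surrogate of
    the forward map, and weighted bounded nonlinear least-squares inverse
    calibration with multistart. A synthetic-data generator emulates the
    experimental protocol so the whole pipeline can be exercised without
    access to tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
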