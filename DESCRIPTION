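Package: facedim
Title: Landmark-Based Analysis of Facial and Body Sexual Dimorphism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric-morphometric and anthropometric tools for quantifying
    sexual dimorphism in human faces and bodies from 2D facial landmark data.
    Implements TPS landmark file input/output, generalized Procrustes
    superimposition with minimum-bending-energy sliding of semilandmarks,
    object-symmetry symmetrization, thin-plate-spline warps and deformation
    grids, sequential permutational MANOVA on shape coordinates,
    variance-component repeatability, twelve classical facial indices
    (including six facial width-to-height ratio variants), body-dimorphism
    statistics (Levene-gated t tests, Hedges' g, type III ANCOVA/MANCOVA
    with partial eta squared, forward-Wald stepwise logistic and forward
    stepwise linear regression, cubic age trends), and a calibrated
    synthetic-cohort generator that plants shape effects of known variance
    fractions for validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    car,
    optparse
Config/testthat/edition: 3
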