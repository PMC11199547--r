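Package: spineload
Title: Individualized Multi-Body Trunk Models for Lumbar Load Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates synthetic patient cohorts with correlated sagittal
    alignment and torso-mass morphology, builds simplified sagittal-plane
    rigid-body trunk models at three degrees of morphological
    individualization (fully individualized, uniform spine, uniform torso),
    estimates lumbar muscle forces by static optimization (minimum sum of
    cubed muscle stress under joint-moment balance and a 1 MPa stress bound),
    decomposes joint reactions into functional-spinal-unit compression and
    anterior-posterior shear, and analyses the resulting load tables with
    signed min-max scaling, t-distributed stochastic neighbour embedding and
    standardized multiple regression per level, load case and configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
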