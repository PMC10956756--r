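Package: pelvifem
Title: Finite-Element Simulation of Posterior Sacrospinous Ligament Fixation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static, geometrically nonlinear finite-element analysis of
    the female pelvic system for studying apical prolapse repair by posterior
    sacrospinous ligament fixation (SSF). Provides a parametric synthetic
    pelvic geometry generator (bladder, vagina, rectum, pelvic floor, fasciae,
    support ligaments), a membrane/truss solver with two-term Yeoh
    hyperelasticity under incompressible plane stress, tie constraints and
    surface-traction loading, configurable unilateral/bilateral suture
    fixation at 1-3 cm from the ischial spine, empirical load calibration
    against imaging-derived displacements, and pelvic-organ-descent readout by
    the pubococcygeal-line (PCL) method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
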