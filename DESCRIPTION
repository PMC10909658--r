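Package: stenoflow
Title: Unsteady Casson Blood Flow in a Catheterized, Balloon-Dilated Stenosed Artery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Axisymmetric incompressible flow simulator for blood flow through a
    stenosed coronary artery segment containing a balloon-tipped catheter. Models
    the stenosed outer wall and catheter-plus-balloon inner wall analytically,
    builds a body-fitted structured grid with refinement at the constriction, and
    advances the unsteady Navier-Stokes equations with a regularized Casson
    yield-stress rheology using a CFL-limited projection (pressure-correction)
    scheme implemented in C++. Post-processing provides Stokes stream functions,
    wall shear stress, pressure drops, flow-rate audits and recirculation
    detection; closed-form annular Poiseuille and Buckingham-Reiner Casson tube
    solutions serve as independent verification oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    generics,
    lhs,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
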