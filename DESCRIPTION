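Package: subcell
Title: Mechanochemical Subcellular-Element Model of Crawling Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a single crawling cell as a network of subcellular
    elements connected by Kelvin-Voigt bonds with linear actuators, crawling
    on a flat substrate through stick-slip friction. Overdamped, force-free
    and torque-free particle mechanics are coupled to an excitable PIP2/PIP3
    reaction-diffusion system integrated on the moving particle cloud with a
    moving-particle-semi-implicit (MPS) discrete Laplacian. Includes a
    prescribed sinusoidal-wave driver, periodic and random excitation
    protocols, parameter-scan runners, and an analysis suite for migration
    metrics (per-cycle displacement, mean-square displacement, velocity
    autocorrelation) and traction-force multipoles (monopole, dipole, torque,
    quadrupole) in the velocity-aligned comoving frame.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
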