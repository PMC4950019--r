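Package: erasim
Title: Simulated Contour Erasure via Boundary Adaptation and Brightness Filling-In
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a neural dynamic model of brightness perception in
    which oriented boundary signals, weakened by activity-dependent
    transmitter habituation in a gated dipole circuit, constrain a diffusive
    filling-in process for opponent surface signals.  Provides parametric
    generators for flicker-adaptation stimulus movies (outline crosses,
    blurred surfaces, annuli, disks, polar checkerboards, illusory-contour
    inducers), a deterministic simulation engine with a compiled core, a
    simulated-psychophysics harness that measures contrast thresholds by
    bisection at the filling-in stage, and a command-line interface for
    rendering demos and running threshold batteries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
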