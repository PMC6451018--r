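Package: tasepLK
Title: Steady-State Density Profiles for the Totally Asymmetric Exclusion
    Process with Langmuir Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the one-dimensional totally asymmetric simple
    exclusion process coupled to Langmuir adsorption-desorption kinetics
    (TASEP-LK), a driven lattice gas used to model biomolecular traffic on
    filaments and templates. Provides a continuous-time kinetic Monte Carlo
    simulator with an exact master-equation oracle for small lattices,
    relaxation and continuation solvers for the singular mean-field
    steady-state equation, a renormalization-group resummed closed form for
    the global density profile with boundary-condition fitting and phase
    classification, and scaling-collapse and profile-comparison utilities
    that tie the three routes together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
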