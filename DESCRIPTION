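Package: pathmc
Title: Stochastic Simulation and Statistical Model Checking of Signalling Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building intracellular reaction-network models with
    mass-action and Hill kinetics, simulating them deterministically (ODE) and
    stochastically (Gillespie's direct-method SSA), and verifying temporal
    behaviour by Bayesian statistical model checking of Bounded Linear Temporal
    Logic (BLTL) properties over simulated traces.  Ships a 31-species model of
    HMGB1 signal transduction coupling the RAS-ERK, Rb-E2F and p53-MDM2
    pathways, together with the simulation and verification experiments the
    model supports (baseline oscillations, dose-response sweeps, and a suite of
    seven BLTL properties).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
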