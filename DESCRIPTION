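Package: radchemxt
Title: Radial Reaction-Diffusion Kinetics of Water Radiolysis Tracks
Version: 0.1.0
Authors@R:
    person("radchemxt", "developers", email = "radchemxt@example.org",
           role = c("aut", "cre"))
Description: Evolves per-species radial concentration distributions of
    water-radiolysis products around an ion or electron track from a
    heterogeneous snapshot (~500 ns) into the homogeneous biochemical
    stage (>= 1 ms). The numerical core combines Crank-Nicolson
    cylindrical diffusion with zero-flux boundaries, explicit bin-wise
    mass-action reaction kinetics under operator splitting, a staged
    time-step schedule, and an automatic collapse of flat distributions
    to well-mixed kinetics. Includes the standard ten-species radiolysis
    reaction network with continuum dissolved oxygen via Henry's law,
    G-value and radial observables, dose/fluence/LET geometry, a
    synthetic track generator for testing without a Monte Carlo
    front-end, independent well-mixed oracles (adaptive ODE and
    Gillespie stochastic simulation), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
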