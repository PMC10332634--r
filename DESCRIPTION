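Package: medusim
Title: Physics-Based Simulation of Swarming Jellyfish in Tank Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of jellyfish swarms modelled as active
    Brownian "swarmalator" particles carrying position, orientation, bell
    pulsation phase and an activity state, coupled one-way to a
    two-dimensional incompressible tank flow and an advected prey field.
    Includes a staggered-grid Navier-Stokes solver with successive
    over-relaxation pressure projection (lid-driven cavity, channel and
    double-gyre scenarios), a monotone advection-diffusion prey solver,
    behavioural response mechanisms (counter-current rheotaxis, turbulence
    avoidance, prey search with activity-gated parametric switching),
    stochastic Heun time integration with paired passive-tracer twin
    ensembles, and swarm statistics (indication numbers, hexatic order,
    velocity-flow correlation, spread, avoidance and crossing fractions)
    with Gaussian-kernel ensemble averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
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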