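Package: mesodrift
Title: Mesoscopic Stochastic Simulation of Inhomogeneous Drift-Diffusion-Reaction Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A mesoscopic (compartment-based) Monte Carlo simulator for
    inhomogeneous, non-linear drift-diffusion systems on two-dimensional
    lattices. Transition probabilities are derived from the first-passage-time
    problem of the underlying Ito stochastic differential equation inside each
    subvolume, so that the lattice walk reproduces the macroscopic drift and
    diffusivity exactly; a competing kernel obtained by centered-difference
    discretization of the Fokker-Planck equation is provided for comparison.
    Multiple dimensions are handled by dimensional splitting on a global event
    timeline with an adaptive global-minimum time step for inhomogeneous and
    state-dependent fields. Per-subvolume stochastic chemical kinetics
    (Gillespie direct method) couple to transport by operator splitting. Ships
    a validation suite of analytically solvable benchmarks (biased diffusion,
    geometric Brownian motion, Ornstein-Uhlenbeck, a mean-field non-linear
    model) and a chemotaxis-driven neuron migration application.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
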