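# mesodrift

Mesoscopic Monte Carlo simulation of inhomogeneous, non-linear
drift-diffusion(-reaction) systems on two-dimensional lattices.

Many systems in cell and developmental biology — guided neuron migration,
chemotaxis, trail formation — are governed by Langevin dynamics

    dx = a(x, t) dt + sqrt(2 D(x, t)) dW

in regimes where a deterministic (Fokker-Planck) treatment misses the
stochasticity and particle-tracking is too expensive. `mesodrift` works at
the compartment level: the domain is split into subvolumes, the state is the
integer particle count per subvolume and species, and transport is a lattice
random walk whose jump and rest probabilities are derived from the exact
**first-passage-time (FPT) problem** of the SDE inside each cell. With the
half-Peclet number `b = a h/(2D)`, the kernel is

    p+/-   = 1 / (1 + exp(-/+ a h / D))          (splitting probabilities)
    tau    = (h/a) tanh(b)                        (mean exit time)
    var    = (h^2/D)^2/(4 b^2) (tanh^2 b + tanh(b)/b - 1)
    rest   = var / tau^2,   dt_c = (1 - rest) tau (canonical step)

which reproduces *both* the drift and the diffusivity exactly — a fixed-step
walk without the rest probability gets the diffusivity wrong whenever the
drift is non-zero. Inhomogeneous and state-dependent fields use the global
minimum canonical step with per-cell rescaled probabilities; the moment
identities stay exact at every admissible step. Multiple dimensions are
advanced by dimensional splitting on a global event timeline, per-subvolume
Gillespie chemistry couples in by operator splitting, and a
centered-difference Fokker-Planck kernel (`kernel = "fpe"`) is included for
comparison — it is first-order accurate and visibly worse in drift-dominated
regimes.

The package ships four analytically solvable validation benchmarks
(homogeneous biased diffusion, geometric Brownian motion, an
Ornstein-Uhlenbeck process with a non-diagonal relaxation matrix, and a
mean-field non-linear model) plus a neuron-migration application in which
the guidance protein Slit repels cells leaving a circular explant.

## A worked example

```r
library(mesodrift)
cfg <- benchmark_config("homogeneous", cells_per_dim = 64, runs = 20,
                        seed = 1401)
res <- run_benchmark(cfg)
res$report
#>       problem kernel cells_per_dim parameter runs time      rmse rmse_stderr boundary_mass
#> 1 homogeneous    fpt            64         2   20    2 0.3541226  0.03115173   4.32987e-15
```

Ten thousand particles start in the center cell of a 64 x 64 lattice with
drift (2, 2) and diffusivity (1, 1); 20 runs are averaged and scored against
the drifting-Gaussian solution at t = 2. The ensemble mean deviates from the
closed form by ~0.35 particles RMS per cell (jackknife standard error
~0.03), and the analytic mass outside the domain is ~4e-15, i.e. the stop
time excludes boundary effects by construction.

Lower-level building blocks are exported too:

```r
fpt_splitting_probabilities(1, 1, 1)$p_plus   # 0.7310586
canonical_step(1, 1, 1)                        # $timestep 0.1639534, $rest 0.6452125
```

The migration application:

```r
cfg <- benchmark_config("migration", runs = 20, seed = 7)
run_benchmark(cfg)$report   # asymmetry ~0 at 24 h, positive after Slit at 48 h
```

A thin command-line front end lives at `inst/cli/mesodrift.R`
(`run`, `benchmark`, `validate-kernels` subcommands; YAML configurations as
in `inst/extdata/homogeneous_example.yaml`).

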