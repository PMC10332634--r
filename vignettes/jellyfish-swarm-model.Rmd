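---
title: "An active-particle model of swarming jellyfish: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-particle model of swarming jellyfish: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medusim)
```

## The model

`medusim` simulates a swarm of jellyfish-like agents as over-damped active
Brownian particles that each carry an internal oscillator — "swarmalators".
Each agent `j` holds four dynamical variables: position `x_j` (m),
orientation `theta_j` (rad), bell pulsation phase `phi_j` (rad) and a
scalar activity `A_j >= 0`. Agents are coupled one-way to a 2D
incompressible tank flow `U(x, t)` and to a prey concentration
`F(x, t)` (normalized by its saturation level `F_0`); they sense the flow
velocity, the magnitude of the vorticity `|C| = |dv/dx - du/dy|` (a local
proxy for turbulence intensity) and the prey gradient, all interpolated
bilinearly to their positions.

**Position.** `dx/dt = U + V(phi, |U|, A) e(theta) + I(x) + F_wall`.
Propulsion acts along the orientation vector `e(theta)` with speed

    V = (V_0 + R(V_a, V_b, |U| + A)) * beta(phi),
    beta(phi) = exp[J (cos(phi) - 1)],

so the bell stroke modulates the speed periodically; at the default shape
`J = 1` the stroke's duty factor (the period average of `beta`) is
`exp(-1) I_0(1) = 0.4658`. `R(a, b, S) = a S / (b + S)` is the single
saturating response function used for every behavioural response in the
model. Activity is added to the flow speed inside the speed response —
the two stimuli are treated as numerically commensurate, which is the
model's own convention and is kept as such. `I(x)` is a fluid-like
soft-core repulsion between agents within the interaction radius `R_i`
(magnitude `R_i/d`, i.e. 1 at the cutoff), averaged over neighbours; an
attractive branch exists behind a toggle but is off by default. Walls
repel per-axis with the same `R_w/d` law inside the wall radius `R_w`.

**Orientation.** `dtheta/dt = L + eps_U sin(theta - delta_U) +
eps_C sin(theta - delta_C) - eps_F sin(theta - delta_F)`, where the
`delta` angles are the full-quadrant directions of the flow, of the
ascending `|C|` gradient and of the ascending prey gradient. With only
the flow term the stable orientation is anti-parallel to the current
(counter-current swimming, i.e. rheotaxis); the vorticity term steers
agents down-gradient of turbulence; the prey term steers towards food.
`L` is a colored (Ornstein–Uhlenbeck) angular drift,
`dL = -lambda_theta L dt + sqrt(2 D(A)) dW`, whose stationary standard
deviation `sqrt(D/lambda_theta)` sets the tumbling intensity.

**Phase and activity.** `dphi/dt = omega(A)` (direct phase coupling
between agents is set to zero in this model; the toggle exists but is a
disabled stub). `dA/dt = -lambda_A A + |grad F| * rectifier(theta -
delta_F)`: activity is excited only while swimming towards the prey
gradient, and decays on a ~3-minute timescale.

**Parametric switching.** Activity and ambient prey re-weight the
couplings:

    eps_U(F) = eps_U0 [1 - R(1, f_U, F)]
    eps_C(A) = eps_C0 [1 - R(1, f_C, A)]
    eps_F(A) = eps_F0 R(1, f_F, A) [1 - R(1, f_g, A)]

so an inactive agent swims against the current and avoids turbulence; a
prey-stimulated agent loses interest in turbulence avoidance, turns
towards prey and, as the ambient concentration rises, gradually releases
its counter-current orientation; at extreme activity (`f_g = 100`) it
lets go of the prey orientation too and floats freely. At `F = 0.3 F_0`
the counter-current weakening is 86% for the default slope `f_U = 0.05`
(97%, 75% and 38% for slopes 0.01, 0.1 and 0.5) — these closed-form
percentages double as calibration anchors in the test suite.

## Fluid and prey solvers

The tank flow comes from the incompressible Navier–Stokes equations on a
staggered marker-and-cell grid: an explicit second-order
advection–diffusion predictor (Adams–Bashforth-2 in time, central
differences in space), a pressure Poisson solve by red–black successive
over-relaxation (SOR), and a Chorin projection that restores a discretely
divergence-free field at every step. Three scenarios are built in:

* **cavity** — 10 m x 10 m, top lid moving at 0.4 m/s in +x (a single
  clockwise gyre);
* **channel** — 40 m x 5 m, fully developed Poiseuille inflow at the +x
  end with peak −0.045 m/s, zero-gradient outflow, giving `Re =
  rho U L / mu = 4500` with the default fluid parameters
  (`rho = 1000 kg/m^3`, `mu = 0.4 N s/m^2`);
* **double gyre** — 10 m x 5 m, both side walls moving upward at
  0.4 m/s, producing two counter-rotating gyres separated by a central
  flow barrier at `x = 0`.

With the default cavity scales, `rho U L / mu = 10^4`. Grid spacing is a
common 0.125 m (channel 321 x 41 nodes per its reference resolution;
cavity 81 x 81 and double gyre 81 x 41 follow the same spacing
convention, since only the domain sizes are prescribed). The fluid time
step is 0.001 s. SOR settings (relaxation 1.7, relative residual 1e-4,
at most 10,000 iterations) and the outflow treatment (zero-gradient
velocity, pressure pinned at the exit face) are solver choices of this
package; they are not externally prescribed.

The prey field obeys an advection–diffusion equation with
`D_F = 0.001 m^2/s` and no-flux walls. The step is conservative
flux-form: MUSCL reconstruction with a van Leer slope limiter for
advection (second-order, monotone — concentrations cannot go negative,
and total mass is conserved to round-off) plus central-difference
diffusion. The foraging initial condition saturates the left half of the
double-gyre tank (`F = F_0` for `x < 0`) with the step smoothed over two
cells by a `tanh` profile to avoid dispersive ringing; prey is neither
consumed nor replenished, so any "leakage" of prey between gyres is
emergent transport, not prescribed.

Because the coupling is one-way (agents do not perturb the fluid), flow
snapshots can be precomputed once per scenario and replayed frozen for
agent ensembles; a `stream_function_flow()` helper builds exactly
divergence-free analytic snapshots (e.g. a double gyre) for tests and
quick experiments, and the channel experiments can use the closed-form
Poiseuille profile directly.

## Time integration and ensembles

Agents advance by a stochastic Heun (predictor–corrector) scheme; the
Wiener increment of the angular noise is drawn once per step and shared
between the two stages, with `D(A)` evaluated at the step's start state.
At the step sizes used (0.001–0.01 s) the difference from the
alternative stochastic-calculus reading of the state-dependent noise is
far below statistical resolution. Orientations are wrapped to
`(-pi, pi]`, phases to `[0, 2*pi)`, and positions are clamped 1e-6 m
inside the tank as a safety net beneath the wall force. Initial
conditions: positions uniform over the scenario's start region (whole
tank, or the right half for foraging), orientations and phases uniform
on the circle, `A = 0`, and `L` drawn from its stationary normal
distribution.

Every run takes a master seed; K-repetition ensembles derive one
sub-seed per repetition, so results are reproducible from `(config,
seed)` alone. A reduced *twin* ensemble — passive tracers (`dx/dt = U +
F_wall`) or repulsive tracers (adding `I(x)`) — can be integrated
alongside the active swarm from identical initial positions; the twin
consumes no random numbers, so its presence leaves the active
trajectories bit-identical. All difference statistics (`delta`-metrics)
are formed against this twin.

## Swarm statistics

* **Indication number** `N(W)`: fraction of agents whose local `W`
  exceeds a threshold, by default the passive-twin mean; ties count as
  not exceeding (a fixed determinism rule for a measure-zero case).
* **Turbulence fraction** `P(|C|) = N(|C|)/N(|C|_passive)` and its
  spike-filtered baseline: drop the first 50 s, then average only
  samples below `0.9 min + 0.1 max`.
* **Crossing fraction** `P(x)`: agents remaining at `x > 0` relative to
  the passive twin.
* **Velocity–flow correlation**: mean of the componentwise Pearson
  correlations between agent velocities and the sampled flow.
* **Hexatic order** `Hex_n`: per agent, the modulus of the average of
  `exp(i 6 delta)` over its `n` nearest neighbours; `n = 6` probes
  crystalline order, `n = 12` resolves filaments. All agents use their
  `n` nearest neighbours regardless of wall proximity (no boundary
  correction), and ties in neighbour distance break by agent index.
* **Spread** `Sigma`: position variance in each direction normalized by
  its initial value (1 at `t = 0`); `Sigma_0` restricts to agents in the
  left gyre.

Ensemble series are double-averaged: Gaussian-kernel temporal smoothing
per run, then the mean over the K runs. The 15-second kernel window is
interpreted as four standard deviations (`sigma = 3.75 s`), truncated at
±2 sigma and renormalized (also at series edges).

## Experiments and default problem sizes

The four scenario pipelines mirror the tank studies: `run_wall_effects()`
(repulsive vs passive tracers, wall interaction distance 0.5 m),
`run_counter_current()` (the reduced rheotaxis model in the channel),
`run_turbulence_avoidance()` (adds the vorticity coupling in the cavity)
and `run_foraging()` (full model in the double gyre, with mechanism
subsets A = frequency + noise responses, B = activity switch-off of
turbulence avoidance with `f_C = 0.02`, C = speed response, D =
everything at the calibrated defaults).

The package defaults run these at desk scale: frozen or analytic flow,
`dt = 0.005 s`, `K = 4` repetitions, N = 128 agents — sizes chosen so a
full counter-current scan point completes in minutes on one core while
its headline number (the counter-current speed fraction at
`eps_U0 = 0.16`, `lambda_theta = 5`) is stable to well under one percent
across seeds. The reference-fidelity settings (live CFD at `dt =
0.001 s`, `K = 16`, 900 s runs) remain available through the
configuration. The measurand of the counter-current experiment is the
time average, over the central two-thirds of the run, of the magnitude
of the ensemble-mean of the agents' velocity relative to their local
flow, divided by the still-water speed 0.067 m/s; subtracting the local
flow per agent *before* ensemble averaging is the reading that makes the
0.087 m/s speed calibration self-consistent.

## Numerical choices and degenerate inputs

* Direction angles come from the full-quadrant arctangent of the vector
  components; a bare tangent is sign-ambiguous.
* When a stimulus direction is undefined (flow speed, `|C|`-gradient or
  prey-gradient magnitude below 1e-8 in native units), the corresponding
  coupling term is dropped for that step rather than evaluated at an
  arbitrary angle.
* Coincident agents (closer than 1e-9 m) repel at the capped magnitude
  `R_i/1e-9` in a random direction drawn from the run's seeded stream.
* The wall force is per-axis ("one-dimensional"), so a corner pushes
  along both normals; it reaches magnitude 1 exactly at the cutoff.
* Activity stays non-negative under Heun stepping at `dt <= 0.01 s`
  because its input is non-negative and its decay is linear.

## What the synthetic conditions do and do not show

All inputs are generated: analytic or solver-produced tank flows,
programmatic prey profiles, and seeded agent ensembles. These emulate
controlled tank experiments — steady driving, a single prey species with
passive Fickian spreading, two-dimensional motion, and moderate swarm
sizes (N = 128–512). They do not emulate open-ocean turbulence spectra,
vertical migration, density stratification, prey behaviour, or
hydrodynamic agent–agent coupling (vortex-ring communication), and the
bell phase has no direct mechanical effect beyond speed modulation.
Passing tests therefore validate the model's internal consistency and
its calibrated responses under these idealized conditions, not
field-scale predictive skill.

## Known limitations

* The cavity and double-gyre flows at these Reynolds numbers are
  unsteady; frozen-snapshot replay trades that time dependence for a
  large speed-up in ensemble scans.
* The hexatic order of boundary agents is diluted by construction (their
  "neighbours" cannot form a closed shell); only interior agents of a
  perfect lattice score exactly 1.
* Long-horizon behaviour (beyond ~15 simulated minutes) and
  first-passage statistics are out of scope.
* The attraction branch of the pairwise interaction and direct bell
  phase coupling are stubs, kept switched off to match the model
  definition.
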