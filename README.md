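# medusim

Physics-based simulation of swarming jellyfish in tank flows.

`medusim` is for quantitative ecologists and active-matter researchers who
want a mechanistic, testable model of jellyfish swarm behaviour: how a
swarm swims against a current, avoids turbulent flow regions, and crosses
a flow barrier to reach prey. Each jellyfish is an over-damped active
Brownian particle carrying an internal bell-pulsation oscillator (a
"swarmalator") and an activity state, coupled one-way to a 2D
incompressible tank flow and an advected prey field.

## The model in brief

Per agent *j*, four variables — position **x**, orientation θ, bell phase
φ, activity A:

    dx/dt     = U + (V0 + R(Va, Vb, |U| + A)) β(φ) e(θ) + I(x) + F_wall
    dθ/dt     = L + ε_U sin(θ − δ_U) + ε_|C| sin(θ − δ_|C|) − ε_F sin(θ − δ_F)
    dφ/dt     = ω0 [1 + R(f_φ, f_φ, A)]
    dA/dt     = −λ_A A + |∇F| · ½(|cos(θ − δ_F)| + cos(θ − δ_F))

with the saturating response `R(a, b, S) = aS/(b + S)`, the bell stroke
factor `β(φ) = exp[J(cos φ − 1)]`, colored angular noise
`dL = −λ_θ L dt + √(2D(A)) dW`, soft-core repulsion `I`, and per-axis
wall forces. The δ angles are the local directions of the flow, of the
absolute-vorticity gradient (a turbulence proxy) and of the prey
gradient; activity and ambient prey re-weight the couplings
(`ε_U(F)`, `ε_|C|(A)`, `ε_F(A)`), producing a behavioural cascade from
counter-current swimming through turbulence avoidance to directed prey
search. The tank flow comes from a staggered-grid Navier–Stokes solver
with SOR pressure projection (lid-driven cavity, Poiseuille channel at
Re = 4500, and a double-gyre tank); prey follows a conservative
monotone advection–diffusion scheme. Ensembles integrate with a
stochastic Heun scheme alongside passive-tracer twins, and swarm
statistics (indication numbers, hexatic order, velocity–flow
correlation, spread, crossing fractions) are averaged over K seeded
repetitions with Gaussian-kernel smoothing.

See the methods vignette (`vignettes/jellyfish-swarm-model.Rmd`) for the
full account of the model, parameters and numerical choices.

## Worked example: counter-current swimming

The channel experiment measures the fraction of the still-water swimming
speed (0.067 m/s) that agents retain while swimming against a 0.045 m/s
Poiseuille current:

```r
library(medusim)
res <- run_counter_current(eps_U0 = c(0.01, 0.16), lambda_theta = 5,
                           N = 64, K = 2, t_total = 120, dt_agent = 0.005,
                           seed = 7)
print(res, digits = 3)
#>   eps_U0 lambda_theta speed_fraction      sd
#> 1   0.01            5          0.256 0.12222
#> 2   0.16            5          1.171 0.00925
```

At weak flow-alignment coupling (`eps_U0 = 0.01` rad/s, below the noise
scale `sqrt(D0/lambda_theta) = 0.14` rad/s) the swarm tumbles and makes
little headway — it keeps only ~26% of its still-water speed. At the
calibrated coupling 0.16 rad/s the swarm locks anti-parallel to the flow
and swims ~17% *faster* than in still water (the full-size run — N = 128,
300 s, K = 4 — gives ~18–21%), because the speed response
`R(V_a, V_b, |U|)` rewards swimming in a current. The closed-form pieces
behind that calibration:

```r
bell_beta_mean(1)                                          # 0.4658
(0.15 + response(0.5, 0.6, 0.045)) * bell_beta_mean(1)     # 0.0861 m/s
```

i.e. the bell stroke has a 0.47 duty factor and the calibrated mean
swimming speed against a 0.045 m/s current is ≈ 0.087 m/s.

Other entry points: `run_wall_effects()`, `run_turbulence_avoidance()`,
`run_foraging()` (the four tank experiments), `run_simulation()` /
`run_ensemble()` for custom configurations, `step_flow()` /
`step_prey()` for the field solvers, and `load_config()` /
`write_outputs()` for YAML-configured, fully reproducible runs. A thin
command-line wrapper ships in `inst/cli/medusim.R`:

```sh
Rscript inst/cli/medusim.R run counter_current --seed 1 --out out/
```

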