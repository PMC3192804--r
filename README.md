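# reachioc

Inverse optimal control of redundant arm reaching, in R.

When a person reaches from rest to touch a **vertical bar**, the task fixes
the horizontal distance but leaves the arrival height free. Different
movement costs resolve this redundancy differently — a hand-smoothness
optimizer stays level, a torque minimizer lets gravity pull the arm down —
so the redundant task discriminates between candidate cost functions far
better than classical point-to-point reaching. `reachioc` implements the
full computational chain for studying this question:

- a **planar two-link arm** (shoulder + elbow) under gravity,
  `τ = M(q)q̈ + C(q, q̇)q̇ + G(q) + Bq̇`, actuated through the motor command
  `u = τ̈`;
- the **eight classical movement costs** — integrated squared hand jerk,
  joint jerk, joint acceleration, torque change, torque; configuration-space
  geodesic length `∫√(q̇ᵀM(q)q̇) dt`; total absolute work `∫Σᵢ|τᵢq̇ᵢ| dt`;
  squared motor command — and their weighted composites
  `C(α) = Σᵢ αᵢ sᵢ Cᵢ`;
- a **direct optimal-control solver** (inverse-dynamics spline
  transcription: boundary-conforming B-spline joint paths, torques recovered
  exactly by inverse dynamics, quasi-Newton optimization with batched
  gradients) for rest-to-rest point and bar tasks;
- **bi-level inverse optimal control**: an outer derivative-free
  trust-region search (BOBYQA) over the cost weights, whose objective
  `Φ(α)` solves one inner optimal-control problem per observed posture and
  measures the Cartesian + curvature mismatch to the observations;
- a **motion-analysis toolbox** (zero-phase Butterworth filtering, 5 %
  speed-threshold segmentation, speed-shape and curvature indices,
  endpoint-consistency index, Monte-Carlo area between paths);
- a **synthetic-data generator** reproducing the statistical structure of
  recorded reaching sessions (bell-shaped speed profiles, anisotropic
  endpoint scatter on the bar, trial-to-trial kinematic and duration
  noise), so the estimation machinery is testable end-to-end against known
  ground truth.

It is aimed at computational motor-control researchers who want to
simulate cost-based movement planning, benchmark inverse optimal control
procedures, or analyze planar reaching kinematics.

## Worked example

Solve the bar-reaching problem for the hybrid cost (absolute work and
angular acceleration at a 10:1 raw weight ratio), then recover the weights
from the synthetic observations it generates:

```r
library(reachioc)
par   <- arm_params()                       # 70 kg, 1.75 m subject
tasks <- default_postures(par)[c("P2", "P3")]
opts  <- solver_options(nodes = 24, eps_schedule = c(1e-2, 1e-4))

s <- compute_rescaling(tasks, par, opts)    # put the 8 costs on one scale
w <- hybrid_weights(s)                      # energy:acceleration = 10:1

sol <- solve_ocp(tasks$P2, w, par, opts)
sol
#> ocp_solution [success]: cost = 5.9438, z_f = -0.074 m, residuals 0.0e+00/0.0e+00/1.1e-16
#>   contributions: angle_accel 10.6%, energy 89.4%

summarize_trajectory(sol$trajectory, tasks$P2, par)
#> movement summary: MD=0.700 s, PV=0.826 m/s, shape=1.625, TPV=0.47, CD=0.356 m
#>   RP=-0.097, MV=-47.3 deg, sIPC=+0.102, coupling R2=0.564
```

The movement starts just above shoulder level (posture P2), and the hybrid
cost sends the fingertip *down* the bar (`z_f = -0.074` m, movement vector
−47°, reached point at −9.7 % of arm length below the shoulder): the
energy term exploits gravity, while the acceleration term keeps the speed
profile single-peaked and bell-shaped (peak at 47 % of the movement). The
path is gently concave (sIPC +0.10) and the residuals confirm the arrival
is at rest on the bar to machine precision.

Now generate a noise-free synthetic "recording" from these weights and
invert it:

```r
obs <- generate_observations(w, tasks, noise_model(0, 0, 0, 0, seed = 7),
                             n_trials = 2, params = par, options = opts)
fit <- fit_weights(obs, inverse_config(budget = 100, restarts = 2, seed = 1),
                   par, solver_options(nodes = 24, maxit = 150,
                                       eps_schedule = c(1e-2, 1e-4),
                                       factr = 1e8), s = s)
round(fit$contributions, 2)
#>     hand_jerk    angle_jerk   angle_accel torque_change        torque
#>          0.08          0.01          0.02          0.01          0.03
#>      geodesic        energy        effort
#>          0.02          0.78          0.05
```

The inversion attributes the movement cost to the energy + joint-smoothness
family (0.81 jointly, energy alone 0.78), matching the generating hybrid
cost; the remaining components are residual. `fit$phi` (here 0.044 m)
reports the fitting error in meters (mean fingertip distance + curvature
mismatch, summed over postures).

A command-line entry point wrapping the same functions lives at
`inst/cli/reachioc.R`:

```sh
Rscript inst/cli/reachioc.R generate --config run.yaml --out obs/ --seed 1
Rscript inst/cli/reachioc.R analyze  --config run.yaml --out results/
Rscript inst/cli/reachioc.R fit      --config run.yaml --out results/ --budget 150
Rscript inst/cli/reachioc.R demo-fig1 --out results/
```

See the methods vignette (`vignettes/reachioc-methods.Rmd`) for the model,
the transcription, the inversion design and its identifiability limits.

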