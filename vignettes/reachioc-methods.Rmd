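---
title: "Inverse optimal control of redundant arm reaching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse optimal control of redundant arm reaching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(reachioc)
```

## The scientific problem

When a person reaches from a resting posture to touch a vertical bar, the
task leaves the arrival height free: infinitely many movements accomplish
the task. Which movement the central nervous system selects is informative
about the *movement cost* it optimizes. This package implements the full
computational chain needed to study that question in a planar arm model:

1. a two-joint (shoulder, elbow) rigid-body arm moving in the vertical
   plane under gravity, actuated through a torque-derivative motor command;
2. eight classical movement cost functionals and their non-negative linear
   combinations;
3. a direct optimal-control solver producing the cost-minimizing
   rest-to-rest movement toward a point or toward the bar manifold;
4. a bi-level *inverse* optimal-control procedure recovering the weight
   vector over the eight costs that best explains observed trajectories;
5. a motion-analysis toolbox (filtering, segmentation, curvature and
   consistency indices, Monte-Carlo path-area comparison);
6. a synthetic-data generator that emulates the statistical structure of
   recorded reaching sessions, so the whole chain is testable end-to-end
   with known ground truth.

## Arm model

The state is $(q, \dot q, \tau, \dot\tau)$ with joint angles
$q = (q_1, q_2)$ (shoulder angle counterclockwise from the forward
horizontal axis; elbow flexion from the extended forearm). Rigid-body
dynamics follow the standard two-link form
$$\tau = M(q)\,\ddot q + C(q, \dot q)\,\dot q + G(q) + B\,\dot q,$$
with the inertia matrix $M$, Coriolis/centripetal terms $C$, gravity
vector $G$ and a joint viscosity matrix $B$. The motor command is the
torque acceleration, $u = \ddot\tau$, a smooth-actuation abstraction that
puts kinematic, dynamic, energetic and neural cost models in a single
framework.

Anthropometry defaults to Winter-style scaling from body mass (70 kg) and
height (1.75 m): segment masses $0.028\,M_b$ and $0.022\,M_b$, lengths
$0.186\,H$ and $0.254\,H$ (forearm+hand, fingertip at its distal end),
centre-of-mass offsets at 43.6% / 68.2% of segment length, and radii of
gyration 0.322 / 0.468 of segment length. The viscosity default is
$B = \begin{pmatrix}0.05 & 0.025\\ 0.025 & 0.05\end{pmatrix}$ N m s/rad, a
common arm-model value. Joint limits default to $q_1 \in [-\pi/2, \pi]$,
$q_2 \in [0, 2.8]$ rad and $|u| \le 10^4$ N m/s$^2$. All of these are
stand-ins for subject-specific measurements and are overridable in
`arm_params()`; none of the qualitative results below depend on their
exact values.

## The eight basis costs

All costs are time integrals over the movement `[0, T]`:

| id | integrand | class |
|----|-----------|-------|
| `hand_jerk` | squared fingertip jerk | kinematic, extrinsic |
| `angle_jerk` | squared joint jerk | kinematic, intrinsic |
| `angle_accel` | squared joint acceleration | kinematic, intrinsic |
| `torque_change` | squared torque rate | dynamic |
| `torque` | squared torque | dynamic |
| `geodesic` | $\sqrt{\dot q^\top M(q) \dot q}$ | path length in the kinetic-energy metric |
| `energy` | $\sum_i \lvert \tau_i \dot q_i \rvert$ | total absolute work (mechanical energy actually spent) |
| `effort` | squared motor command $\lVert \ddot\tau \rVert^2$ | neural |

A composite cost is $C(\alpha) = \sum_i \alpha_i s_i C_i$ with
$\alpha \ge 0$. The re-scaling vector $s$ (from `compute_rescaling()`)
equalizes the wildly different magnitudes of the basis costs: $s_i$ is the
reciprocal of the median single-cost optimal value over a set of
point-to-point tasks, so re-scaled single-cost optima are all $O(1)$.

The geodesic integrand uses the metric length form
$\sqrt{\dot q^\top M \dot q}$ (the configuration-space path length under
the inertia metric), and the neural command is identified with
$u = \ddot\tau$, consistent with the actuator model. The two
nondifferentiable integrands (geodesic, absolute work) are smoothed with a
parameter $\varepsilon$ ($\sqrt{x^2 + \varepsilon^2}$-type); the exact
costs are the $\varepsilon \to 0$ limits, and the solver uses a
continuation schedule $10^{-2} \to 10^{-6}$ (SI-scaled).

## Direct solver: inverse-dynamics spline transcription

The rest-to-rest problem is: find the trajectory of the actuated arm that
starts at rest in posture $q_0$ (zero velocity, gravity-compensating
torque, zero torque rate), arrives *at rest* on the target after exactly
$T$ seconds (zero velocity and zero acceleration at contact; the terminal
torque rate is left free), and minimizes the composite cost. For a bar
target only the horizontal fingertip coordinate is constrained at arrival;
the height on the bar is part of the unknowns.

The solver parameterizes the *joint path* and recovers everything else by
inverse dynamics:

- Each joint angle is a degree-6 polynomial ramp (matching all boundary
  conditions exactly) plus a combination of degree-6 B-splines whose value
  and first three derivatives vanish at the start and whose value and
  first two derivatives vanish at the end. Boundary conditions therefore
  hold to machine precision, and torques, torque rates and motor commands
  follow from the joint path analytically - the dynamics are satisfied by
  construction, with no defect constraints left for the optimizer.
- The remaining unknowns are the spline coefficients (and, for a bar
  task, the arrival height), a smooth bound-constrained problem solved by
  L-BFGS-B with batched central-difference gradients.
- Costs are integrated with a composite Gauss-Legendre rule, a fixed-order
  panel on every knot interval.

Numerical design choices that matter, all of which were driven by
verifiable failure modes:

- **Knot layout.** The zero-initial-jerk rest condition induces a thin
  boundary layer: the true minimizers of jerk-type costs approach profiles
  with nonzero initial jerk, which a conforming basis can only imitate in
  a rapidly refined region near $t = 0$. Three geometrically graded knots
  at each end (down to $\sim 10^{-3}$ of the movement) resolve the layer;
  the remaining knots are uniform so the mid-movement path keeps full
  resolution. With the default basis the solver reproduces the analytic
  minimum-jerk movement to 0.2% in cost, 0.13 mm in path, and 0.001 in
  the peak/mean speed ratio.
- **Basis normalization.** Each basis function is divided by its jerk
  seminorm; without this the Hessian of smoothness costs spans ~12 orders
  of magnitude and quasi-Newton iteration stalls.
- **Quadrature.** At least 7 Gauss points per knot interval: a degree-6
  spline piece cannot vanish at 7 points, so a discretized minimizer of a
  rest-rewarding integrand (absolute work is zero wherever the arm does
  not move) cannot "park" on the quadrature nodes while oscillating
  between them.
- **Regularization of purely nonsmooth objectives.** When the
  differentiable derivative-penalty terms contribute essentially nothing
  (pure geodesic or pure absolute-work problems), a small acceleration
  regularizer (0.1% of the initial objective; excluded from reported
  costs) suppresses the residual node-dodging freedom.
- **Negligible-term dropping.** Cost components contributing less than
  0.1% of the composite at the initial guess are dropped from the working
  objective. They cannot move the optimum beyond solver resolution, but
  kinked integrands with microscopic weights act as "sandpaper" that
  stalls line searches far from the smooth minimum - and, worse, makes the
  inner solutions discontinuous in the weights, which the outer inverse
  loop cannot tolerate. Reported costs always use the caller's weights.
- **Endpoint multistart.** Several costs are multimodal in the arrival
  height (a torque-minimizing movement may either stay level or descend
  and let gravity work). Cold bar solves try the start height and two
  spread heights and keep the best.

The returned solution reports the trajectory on a uniform grid, the
composite and per-basis costs evaluated on the solver's quadrature grid
(a uniform grid cannot see the boundary-layer jerk), terminal residuals,
and the spline coefficients for warm starting.

## Bi-level inversion

Given per-posture reference trajectories, `fit_weights()` minimizes
$$\Phi(\alpha) = \sum_{\text{postures}} d\big(x_\alpha, x_{\text{obs}}\big),$$
where $x_\alpha$ is the inner optimal trajectory and $d$ is the
trajectory metric: mean pointwise fingertip distance plus
$\lambda_c \,\lvert \Delta \text{sIPC} \rvert \cdot \text{chord}$ (both
terms in meters; $\lambda_c = 1$ by default). One weight component is
anchored at 1 - composite costs are identified only up to a positive
factor - with the angular-acceleration component as the default anchor.

The outer optimizer is BOBYQA, a bound-constrained derivative-free
trust-region method with quadratic local models, run from an all-ones
start plus random restarts. Design choices:

- **Log-scale search.** The informative region of $\Phi$ is where some
  weights become negligible; on a linear scale this is a thin funnel in a
  large flat plateau. The free weights are searched as $\log_{10}\alpha$
  over $[10^{-6}, 10^{2}]$, which spreads the funnel evenly. A weight at
  the lower floor is effectively absent (and is dropped by the inner
  solver's negligible-term rule, so the floor is *exactly* equivalent to
  zero).
- **Warm starts.** Inner solves start from the solution kept at the best
  weight vector seen so far; this keeps $\Phi$ evaluations cheap
  (milliseconds against seconds) and nearly deterministic. The reported
  $\Phi$ at the fitted weights is always recomputed from scratch.
- Reported outputs include raw weights (anchor = 1), sum-normalized
  weights, and per-cost *contributions*
  $\alpha_i s_i C_i / \sum_j \alpha_j s_j C_j$ - the weights alone do not
  reveal how much each ingredient shapes the movement.

### What inversion can and cannot identify

Two structural degeneracies, both verified numerically, limit parameter
recovery regardless of the optimizer:

- **Redundancy-direction flatness.** For weakly endpoint-selective costs
  (pure angular acceleration is the extreme case) the optimal cost is
  nearly constant over centimetres of arrival height. The observed
  endpoint then carries almost no usable information: perturbing the
  weight vector by parts in $10^4$ moves the predicted endpoint by more
  than the fitting-error scale, and mixtures that pin the endpoint
  through other components can fit *better* than the ground-truth weight
  vector. Contribution recovery for such costs from bar observations is
  therefore not expected, and the package's tests exercise recovery where
  it is identifiable (endpoint-selective costs such as the hand-jerk and
  the energy-dominated hybrid).
- **Intra-class substitution.** Angle jerk and angle acceleration (and to
  a lesser degree the energy/torque pair on descending movements) produce
  very similar trajectories; only grouped contributions (e.g. "joint
  smoothness" = jerk + acceleration) are robustly attributable.

These are properties of the scientific problem, not artifacts: the
redundant bar paradigm discriminates cost families precisely because
different costs select different endpoints, and conversely a cost that
does not care about the endpoint is hard to identify from endpoint data.

## Motion analysis

`preprocess()` mirrors a standard motion-capture chain: zero-phase
5th-order Butterworth filtering at 10 Hz (applied forward-backward, so
the effective order doubles; the record is reflection-padded and centred
so start-up transients stay outside the window), movement segmentation at
5% of peak tangential speed (the contiguous above-threshold run containing
the global peak, which makes the window robust to threshold crossings
caused by pre-movement noise), and time normalization to 200 samples with
cubic splines. Curvilinear distance is integrated on the filtered
pre-resampling grid. Note that 5%-of-peak trimming of an ideal quintic
retains 88.8% of the nominal duration - measured movement durations are
operational quantities, shorter than the planning horizon by construction.

`summarize_trajectory()` computes movement duration, peak/mean speed and
their ratio (1.875 for a minimum-jerk quintic), relative time to peak
speed, curvilinear distance, the reached point normalized by arm length,
the movement-vector angle, the signed index of path curvature (maximum
chord deviation over chord length, positive above the chord), and
shoulder-elbow coupling; with repeated trials it adds endpoint constant
and variable errors and the consistency index (endpoint SD along the bar
over the reachable-region length, the fraction of available redundancy
actually used).

`area_between_paths()` estimates the area enclosed between two paths by
Monte-Carlo sampling of the joint bounding box with even-odd
point-in-polygon tests, reporting a binomial standard error; identical
paths short-circuit to zero.

## Synthetic data

`generate_observations()` emulates a recording session: the bar problem is
solved under the ground-truth weights; each trial jitters the endpoint
(Gaussian, vertical SD 0.03 m and antero-posterior SD 0.01 m by default -
the 3:1 anisotropy observed in such tasks), warps the nominal path toward
the jittered endpoint with a quintic ramp (or optionally re-solves a
fixed-endpoint problem per trial), adds a smooth path perturbation built
from the first three sine half-waves (amplitude 5 mm; the basis vanishes
at both endpoints in position, leaving a small residual endpoint
velocity), and scales the duration (CV 0.1). The five default postures
P1-P5 span start positions above, level with and below the shoulder,
expressed as fractions of arm length so they adapt to any subject; the bar
sits at 85% of arm length and movements last 0.7 s by default. What this
generator does *not* emulate: marker noise spectra, soft-tissue artifacts,
signal-dependent motor noise, or any within-trial feedback corrections -
so passing recovery tests demonstrate the correctness of the estimation
machinery on data satisfying the model's assumptions, not robustness to
every feature of real recordings.

## Problem sizes used in the test-suite and acceptance runs

Solver defaults use a 40-node discretization (10 free spline functions
per joint); inversion tests run at 24 nodes with two postures, trust-region
budgets of 100-150 inner solves and 2-3 restarts; Monte-Carlo areas use
$10^4$-$10^5$ samples. These sizes were chosen so the full pipeline
exercises every code path at comfortable interactive speed; all headline
quantities (minimum-jerk cost, speed-shape ratio, endpoint profiles) are
mesh-converged well below their acceptance tolerances at these sizes.

## Known limitations

- Single-plane, two-joint arm: no wrist, no muscle-level actuation, no
  3-D shoulder kinematics.
- Deterministic planning only; stochastic (variance-based) costs are out
  of scope by design.
- The inner solver finds local minima; the endpoint multistart and warm
  starts make it reliable on reaching-scale problems but global optimality
  is not certified.
- Weight recovery is limited by the identifiability structure discussed
  above; reported contributions should be read at the granularity of cost
  families.
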