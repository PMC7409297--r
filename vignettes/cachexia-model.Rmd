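---
title: "Modelling muscle wasting in cancer cachexia with cachexim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling muscle wasting in cancer cachexia with cachexim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cachexim)
```

## The model and its assumptions

`cachexim` describes skeletal muscle as a two-compartment stem-cell
lineage. Satellite cells `S` divide at rate `ν` and each division is
symmetric: two satellite cells with probability `p`, two myofibers with
probability `1 − p`. Myofibers `M` die at the natural rate `d0`. Both `p`
and `ν` are down-regulated by muscle mass through a Hill-type negative
feedback with a shared half-saturation volume `m`, which is what holds the
tissue at a stable size: homeostasis forces `p = 1/2`, pinning `M` at
`Mss = m (2(p0+p1) − 1)/(1 − 2 p0)` and the stem ratio at
`ψss = 2 d0 p1 / (2 p1 ν0 + (1 − 2 p0) ν1)`, bounded above by `d0/ν0`.

Key simplifications, inherited from the model family and kept here:
intermediate progenitor cells are collapsed into the two compartments;
divisions are strictly symmetric (no asymmetric self-renewal), which makes
the system very sensitive near `p = 1/2`; fiber-diameter atrophy, spatial
structure, inflammation and metabolism are out of scope.

A tumor grows independently of the host tissue by an exponential-linear
law, `dT/dt = μT (1 + (μT/μ1)^η)^(−1/η)`: exponential at rate `μ` below the
threshold `Tth = μ1/μ`, linear at `μ1` above, blended with sharpness
`η = 20`. The tumor perturbs the muscle system through a saturating signal
`T/(m2 + T)` in three ways: it suppresses satellite proliferation by a
factor `1 − ε T/(m2+T)`, kills satellite cells at rate `dS T/(m2+T)`, and
kills muscle at rate `dM T/(m2+T)`. The self-renewal probability `p` is
assumed untouched by the tumor. ActRIIB blockade multiplies `ε`, `dS`,
`dM`, and `d0` by efficacies `A1..A4 ∈ [0,1]` from a start day onward; the
tumor itself is unaffected by treatment, matching the C26 observations.

## Units, conversions, and time origins

Model state is volume in mm³ throughout; grams appear only at I/O
boundaries through `conversion_convention()`: body weight is 40% skeletal
lean mass, split 95% muscle / 5% satellite, converted at ξ = 0.002 g/mm³
(a 1000 mm³ tumor weighs about 2 g). The healthy clock starts at age 3
weeks (day 0); the cachexia/treatment clock starts at tumor implantation,
which is healthy day 49 (a 10-week-old mouse). Trajectory metadata records
which model produced it.

A point worth spelling out because it is easy to get wrong: the commonly
quoted adult reference state `S = 268.01, M = 5088.92` mm³ is *not* the
day-0 state of the healthy solve. Integrating from the lean-rule
deconstruction of the 11.26 g three-week weight (`S = 112.6, M = 2139.4`
mm³) for 49 days lands exactly on that adult state and gives the day-49
stem ratio `ψ49 = 0.05266544`:

```{r psi49}
reference_stem_ratio()
```

Both states are available through `healthy_initial_state(age =)`. The
implantation-day initial conditions for the tumor-bearing cohorts then
follow from each cohort's average day-0 weight while preserving `ψ49`, so
the feedback state is age-appropriate:

```{r ics}
psi49 <- reference_stem_ratio()
initial_conditions_from_weight(cohort_day0_weight("A"), psi49)
initial_conditions_from_weight(cohort_day0_weight("B"), psi49)
```

## Parameters that matter

| Parameter | Meaning | Units | Fitted value |
|---|---|---|---|
| `p0`, `p1` | homeostatic / perturbation self-renewal probability | – | 0.479, 0.133 |
| `ν0`, `ν1` | homeostatic / perturbation division rate | /day | 0.087, 5.591 |
| `d0` | natural muscle death rate | /day | 0.05 |
| `m` | feedback half-saturation volume | mm³ | 1000 |
| `μ`, `μ1`, `η` | tumor growth rates and transition sharpness | /day, mm³/day, – | 0.446, 116.0, 20 |
| `ε`, `dS`, `dM`, `m2` | proliferation suppression, induced death rates, tumor half-saturation | –, /day, /day, mm³ | 0.004, 0.030, 0.104, 338 |
| `A1..A4`, `t_start` | blockade efficacies, treatment start | –, day | (0, 0, 0.51, 0.54) from day 5 (early) or (0, 0, 0.62, 1) from day 14 (late) |

All constructors validate eagerly with named-inequality messages because
the system is extremely sensitive near `p = 1/2`: a silently accepted
infeasible bundle surfaces as a baffling blow-up deep in the solver.
Steady-state operations additionally require `p0 < 1/2 < p0 + p1` and name
the violated inequality rather than returning a negative volume; transient
`p(t) > 1/2` during growth is normal and never blocked in simulation.
`Tth` is always recomputed from `μ1/μ`, never stored.

## Numerical choices

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) with
`rtol = 1e-10`, `atol = 1e-12` by default — tight because the day-49 stem
ratio is meaningful to 7 significant figures. The reporting grid never
influences the solution beyond solver tolerance (tested). Large-tumor
evaluation of the growth law is done in log space so `(μT/μ1)^η` cannot
overflow at `η = 20`. Blow-ups and solver failures raise an explicit error
carrying the last good time. Treatment runs solve the untreated system up
to `t_start` and restart the treated system from the switch state, so the
trajectory is continuous by construction; a `from_zero` flag applies the
treatment equations over the whole window instead, since published fits do
not always state which convention they used.

Wound healing (`wound_healing_experiment()`) starts from `χ·(Sss, Mss)` and
defines healing time as the first time `Mss − M(t) < 0.1` (model volume
units by default; pass `threshold = 50` for the 0.1 g reading). The
crossing is resolved by bisection on a locally re-solved segment, not by
grid lookup, so it is independent of the reporting step.

## Calibration pipeline

The pipeline mirrors a three-stage hierarchical design:

1. **Logistic extension** (`fit_logistic()`, `extend_dataset()`): growth
   data cover only ages 3–15 weeks, so a logistic curve (α = 0.0756,
   K = 28.3 g, W0 = 11.26 g fixed to the day-0 observation) is fitted by
   nonlinear least squares and sampled every 10 days out to day 300; the
   extension is what lets the feedback fit see the adult plateau.
2. **Simulated annealing** (`fit_healthy()`): with `d0` and `m` fixed,
   `(p0, p1, ν0, ν1)` minimize the pooled RMSE of muscle-mass and
   stem-mass residuals in grams (unweighted by default; a `stem_weight`
   exists because the stem series is ~19× smaller). An outer loop re-runs
   the annealer over a small `(d0, m)` grid. The annealer uses geometric
   cooling (factor 0.95, 200 temperatures × 50 proposals by default),
   per-parameter Gaussian proposals reflected at the box, and a proposal
   scale that shrinks geometrically so late iterations refine. Because the
   objective has a narrow curved valley that isotropic steps descend very
   slowly, the annealed optimum is finished with a deterministic
   Nelder–Mead polish (`sa_control(polish = TRUE)`, default); annealing
   finds the valley, the polish walks it to the bottom. Every fit records
   its seed and objective trace and re-runs bit-identically.
3. **Grid search** (`fit_tumor()`, `fit_cachexia()`, `fit_treatment()`):
   exhaustive RMSE evaluation over explicit grids, returning the argmin
   *and* the full objective surface. Documented "generous" default grids
   are provided but deliberately coarse grids are fine for exploration;
   boundary argmins are flagged in the diagnostics. The retained surface is
   how the known degeneracy in `ε` is made visible: the fitted `ε = 0.004`
   and `ε = 0` give essentially the same objective, so tumor-induced
   quiescence is not identifiable from lean-mass data alone — the wasting
   signal is carried by the induced death rates.

## What the synthetic cohorts emulate — and what they do not

`generate_healthy_cohort()` draws per-animal weights from the closed-form
logistic curve; `generate_cachexia_cohort()` and
`generate_treatment_cohort()` solve the corresponding ODE systems from
weight-derived initial conditions (0.5 mm³ implant) and reconstruct gross
body weight as `lean/0.4 + ξT`, exactly inverting the lean-mass
deconstruction so that calibration round-trips are lossless at zero noise.
Measurement noise is multiplicative Gaussian on reported weights
(default CV 2%, truncated at ±4σ to preserve positivity) — a scale-error
model chosen because the study reports no noise model. Default schedules
follow the study cadences: weekly to day 84 then every 10 days to 300 for
healthy cohorts; daily over days 0–30 for tumor-bearing ones, with 10
animals per cohort.

The generators deliberately omit between-animal parameter heterogeneity
(random effects), survival/censoring, and any model misspecification.
Passing recovery tests on these cohorts therefore demonstrates that the
pipeline is correct and well-conditioned under the model's own assumptions;
it does not certify performance on real mice, where fiber-diameter atrophy,
fat loss, and inflammation contribute variance the model does not carry.

## Sensitivity analysis

`relative_sensitivity()` implements the one-at-a-time percent change
`100·(y(ρ(1±0.05)) − y(ρ))/y(ρ)`. `healthy_sensitivity_table()` evaluates
it on the closed-form steady state; structural independence (e.g. `Mss`
contains neither `ν0`, `ν1` nor `d0`) is detected from the closed form
itself — an exactly zero change — and reported as `NA` rather than 0. The
+5% perturbation of `p0` crosses the `p0 < 1/2` boundary where the
algebraic "steady state" is negative; the table still reports the resulting
extreme values (≈ +22,542% for `Sss`, −964% for `Mss`) but flags the rows
`unphysical`, which is exactly the behavior a user probing the `p = 1/2`
singularity should see. `cachexia_sensitivity_table()` perturbs the disease
and treatment parameters and re-solves to day 20 post-implantation — inside
the dynamic wasting phase, since the cachectic animal never reaches a
steady state; the evaluation day and solver settings are configurable, and
the reported cells are stable to well under 0.01 percentage points per
decade of solver tolerance.

```{r sens}
healthy_sensitivity_table(fitted_params("healthy"))[, 1:6]
```

## Design choices made where the design was open

- **Initial-condition recipes.** Both the lean-rule deconstruction of a
  weight and the printed adult reference state are exposed; the healthy
  reference solve starts from the three-week lean-rule state because that
  (and only that) reproduces `ψ49` and the adult state simultaneously.
- **Treatment fitting convention.** Piecewise switch-on at `t_start` is
  the default; `from_zero = TRUE` is available for comparison.
- **Healing-time threshold units.** Model volume units (0.1 mm³) by
  default, with the gram interpretation one argument away.
- **Healthy-fit residual units.** Grams, pooled unweighted over muscle and
  stem series; a weight option exists for the scale imbalance.
- **`(d0, m)` outer-loop candidates.** No published set exists; the
  default is a coarse grid around the fitted values, overridable.

## Observed model behavior worth knowing

Two plausible-sounding expectations fail against the actual dynamics, and
the test suite encodes the corrected versions. First, regeneration after
injury is overdamped: after a 30% loss, satellite cells expand and settle
at `Sss` from below rather than overshooting it (the transient "satellite
bump" is relative to the injured level, not to homeostasis). Second, early
treatment dominates late treatment in lean mass only over the ~30-day
observation window; because both treated systems share one equilibrium,
the late-treated cohort's stronger feedback rebound crosses over around
day 33. Healing times grow sub-linearly with injury severity (a 30% injury
heals in less than 3× the time of a 10% injury).

## Problem sizes used by the test suite

Tests run the full pipeline at reduced but honest sizes chosen to exercise
every code path: annealing at 40 temperatures × 15 proposals plus polish
(which recovers the generating parameters exactly on noiseless data),
grid fits on 2–5 values per axis bracketing the truth, noisy-recovery
checks over 50 seeded replicates of 10-animal cohorts at 2% CV, and
100-draw property sweeps for the closed-form invariants. The full suite
completes in well under a minute on one CPU.

## Known limitations

Fitted parameters shipped as fixtures reproduce the published values, but
the underlying digitized mouse data are not machine-readable, so RMSE
values against real data are context, not targets, and cannot be
recomputed here. The model omits fiber-diameter atrophy, progenitor
compartments, asymmetric division, ActRIIA co-blockade, and all
spatial/metabolic/inflammatory couplings; near `p = 1/2` the steady state
is extraordinarily sensitive to `p0`, a structural feature of the symmetric
division assumption rather than a numerical artifact.
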