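# cachexim

Feedback-regulated skeletal-muscle dynamics in health, cancer cachexia, and
ActRIIB-blockade treatment.

Cancer cachexia is an irreversible, tumor-driven loss of skeletal muscle
that worsens survival and blocks therapy. `cachexim` implements a
compartmental stem-cell-lineage model of muscle tissue for researchers in
mathematical oncology and muscle biology: satellite cells (muscle stem
cells) `S(t)` and myofibers `M(t)` interact through negative feedback, a
growing tumor `T(t)` perturbs the feedback, and soluble-ActRIIB treatment
partially lifts the perturbation. The package provides the ODE systems and
their closed-form steady states, numerical simulation and in-silico
experiments (wound healing, mechanism sweeps, treatment timing), a
three-stage calibration pipeline, local sensitivity analysis, and synthetic
mouse-cohort generators so the whole pipeline is testable without animal
data.

## The model

Healthy tissue follows a two-compartment lineage with symmetric division:

    dS/dt = (2 p(M) - 1) ν(M) S
    dM/dt = 2 (1 - p(M)) ν(M) S - d0 M

where the self-renewal probability and division rate are down-regulated by
muscle mass through a shared Hill feedback with half-saturation volume `m`:

    p(M) = p0 + p1 / (1 + M/m),      ν(M) = ν0 + ν1 / (1 + M/m)

Homeostasis forces `p = 1/2`, giving the closed-form steady state

    Mss = m (2(p0 + p1) - 1) / (1 - 2 p0),     ψss = Sss/Mss = 2 d0 p1 / (2 p1 ν0 + (1 - 2 p0) ν1)

The tumor grows exponential-linearly, `dT/dt = μT (1 + (μT/μ1)^η)^(-1/η)`,
and couples to the muscle system through a saturating factor `T/(m2 + T)`
that suppresses satellite proliferation (strength `ε`) and adds death rates
`dS` and `dM` to the two compartments. Treatment scales these mechanisms by
efficacy multipliers `A1..A4 ∈ [0, 1]` (with `A4` acting on the natural
death rate `d0`) from a start day onward. Body weight maps to model volumes
by the 40% lean-mass rule, split 95% muscle / 5% satellite, with
ξ = 0.002 g/mm³.

## Worked example

Simulate the C26 tumor-bearing mouse from its implantation-day state and
compare untreated wasting with early treatment:

```r
library(cachexim)

hp <- fitted_params("healthy")     # p0 = 0.479, p1 = 0.133, nu0 = 0.087, ...
tp <- fitted_params("tumor")       # mu = 0.446 /day, mu1 = 116 mm^3/day
cp <- fitted_params("cachexia")    # eps = 0.004, dS = 0.030, dM = 0.104, m2 = 338

steady_state(hp)
#>         S        M
#>  274.9738 5333.3333
steady_state_stem_ratio(hp)        # 0.0516: about 1 satellite per 19 muscle units
reference_stem_ratio(hp)           # 0.05266544: stem ratio of a 10-week-old mouse

spec <- experiment_spec("cachexia", list(healthy = hp, cachexia = cp, tumor = tp),
                        tissue_state(S = 252.75, M = 4799.25, T = 0.5),
                        times = seq(0, 30, by = 5))
tr <- integrate_model(spec)
round(as.data.frame(tr), 2)
#>   day      S       M       T
#> 1   0 252.75 4799.25    0.50
#> 2   5 257.13 4897.03    4.65
#> 3  10 259.32 4879.79   43.24
#> 4  15 254.56 4368.00  372.33
#> 5  20 248.38 3559.05  952.33
#> 6  25 253.74 3091.99 1532.33
#> 7  30 268.62 2922.38 2112.33
```

Lean mass `ξ (S + M)` falls from 10.10 g to 6.38 g in 30 days — severe
wasting, while the satellite pool is comparatively spared. Starting
treatment on day 5 with the early-cohort efficacies rescues most of it:

```r
tx <- fitted_params("treatment_a")       # A = (0, 0, 0.51, 0.54), t_start = 5
trx <- simulate_treatment(spec, tx)
0.002 * (trx$S[7] + trx$M[7])            # 9.57 g lean mass at day 30
effective_muscle_death(hp, cp, tx)       # 0.08 /day (vs 0.154 untreated)
```

Sensitivity tables, wound-healing experiments, cohort generation and the
calibration fits (`fit_logistic()`, `fit_healthy()`, `fit_tumor()`,
`fit_cachexia()`, `fit_treatment()`) are demonstrated in the vignette
(`vignettes/cachexia-model.Rmd`); one-command stages are available through
`run_pipeline()`.

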