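# Shared fixtures: the fitted C26-study bundles and small generators used
# across the suite.

hp_fit <- fitted_params("healthy")
tp_fit <- fitted_params("tumor")
cp_fit <- fitted_params("cachexia")
tx_a <- fitted_params("treatment_a")
tx_b <- fitted_params("treatment_b")
conv_def <- conversion_convention()

group_a_state <- function(T0 = 0.5) tissue_state(S = 252.75, M = 4799.25, T = T0)

# random healthy parameter bundles admitting a positive steady state
random_homeostatic_params <- function() {
  p0 <- stats::runif(1, 0.30, 0.49)
  p1 <- stats::runif(1, 0.5 - p0 + 0.02, min(1 - p0, 0.6))
  healthy_params(p0, p1,
                 nu0 = stats::runif(1, 0.02, 0.5),
                 nu1 = stats::runif(1, 0.5, 8),
                 d0 = stats::runif(1, 0.01, 0.2),
                 m = stats::runif(1, 200, 5000))
}

# noiseless muscle/stem mass series generated by the healthy model itself
healthy_self_data <- function(hp = hp_fit, days = sort(unique(c(seq(0, 84, 7),
                                                                seq(90, 300, 10))))) {
  spec <- experiment_spec("healthy", list(healthy = hp),
                          healthy_initial_state(), times = days)
  tr <- integrate_model(spec)
  list(muscle = observation_series(days, conv_def$xi * tr$M, "muscle_g"),
       stem = observation_series(days, conv_def$xi * tr$S, "stem_g"),
       trajectory = tr)
}

cachexia_spec <- function(times = seq(0, 30, by = 0.5), state0 = group_a_state(),
                          cp = cp_fit, tp = tp_fit, hp = hp_fit, ...) {
  experiment_spec("cachexia",
                  list(healthy = hp, cachexia = cp, tumor = tp),
                  state0, times, ...)
}
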