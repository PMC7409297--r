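# Synthetic mouse cohorts with the statistical structure the calibration
# pipeline assumes: deterministic model trajectories, deconstructed into
# the observables a scale would report, with multiplicative Gaussian
# measurement noise.

#' Specify a synthetic cohort
#'
#' @param n number of animals, `>= 1`.
#' @param params generating parameter bundle: a [logistic_params()] for
#'   healthy cohorts, or a named list with `healthy`, `cachexia`, `tumor`
#'   (and optionally `treatment`) entries for tumor-bearing cohorts.
#' @param schedule measurement days. Defaults follow the study cadences:
#'   healthy weekly to day 84 then every 10 days to day 300;
#'   cachexia/treatment daily over days 0-30.
#' @param cv coefficient of variation of the multiplicative Gaussian
#'   measurement noise on reported weights (default 0.02; 0 disables
#'   noise). Draws are truncated at 4 standard deviations so weights stay
#'   positive.
#' @param seed integer RNG seed; the same spec always generates the same
#'   cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, params, schedule, cv = 0.02, seed = 1L) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (length(schedule) == 0) stop("schedule must be non-empty", call. = FALSE)
  structure(list(n = as.integer(n), params = params,
                 schedule = as.numeric(schedule), cv = cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  z <- stats::rnorm(n)
  z <- pmin(pmax(z, -4), 4)  # truncate to keep reported weights positive
  1 + cv * z
}

#' Generate a healthy body-weight cohort
#'
#' Samples each animal's weight from the closed-form logistic growth curve
#' times independent multiplicative noise, and returns the per-animal
#' series together with the cohort mean series (the observable the healthy
#' calibration consumes).
#'
#' @param spec a [cohort_spec()] whose `params` is a [logistic_params()].
#' @return A list: `animals` (data frame `animal_id`, `day`, `weight_g`),
#'   `mean_series` (an [observation_series()] of per-day cohort means), and
#'   `truth` (the noiseless curve).
#' @export
generate_healthy_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(spec$params, "logistic_params"))
  set.seed(spec$seed)
  days <- spec$schedule
  truth <- logistic_weight(days, spec$params)
  animals <- do.call(rbind, lapply(seq_len(spec$n), function(a) {
    data.frame(animal_id = a, day = days,
               weight_g = truth * .noise_factor(length(days), spec$cv))
  }))
  mean_w <- tapply(animals$weight_g, animals$day, mean)
  list(animals = animals,
       mean_series = observation_series(as.numeric(names(mean_w)),
                                        as.numeric(mean_w),
                                        kind = "body_weight_g"),
       truth = observation_series(days, truth, kind = "body_weight_g"))
}

.cohort_solve <- function(spec, day0_weight, psi_ref, conv, T0, treated) {
  p <- spec$params
  ic <- initial_conditions_from_weight(day0_weight, psi_ref, conv)
  state0 <- tissue_state(S = ic[["S"]], M = ic[["M"]], T = T0)
  times <- sort(unique(c(0, spec$schedule)))
  espec <- experiment_spec("cachexia",
                           list(healthy = p$healthy, cachexia = p$cachexia,
                                tumor = p$tumor, treatment = p$treatment),
                           state0, times)
  traj <- if (treated) simulate_treatment(espec) else integrate_model(espec)
  idx <- match(spec$schedule, traj$times)
  lean <- conv$xi * (traj$S[idx] + traj$M[idx])
  tumor <- traj$T[idx]
  # gross weight as a scale would see it: lean scaled back up by the lean
  # fraction, plus the tumor mass; inverts the lean deconstruction exactly
  weight <- lean / conv$lean_fraction + conv$xi * tumor
  list(lean = lean, tumor = tumor, weight = weight, traj = traj)
}

.cohort_output <- function(spec, sol) {
  set.seed(spec$seed)
  days <- spec$schedule
  animals <- do.call(rbind, lapply(seq_len(spec$n), function(a) {
    data.frame(animal_id = a, day = days,
               weight_g = sol$weight * .noise_factor(length(days), spec$cv))
  }))
  list(animals = animals,
       lean_series = observation_series(days, sol$lean, "lean_mass_g"),
       weight_series = observation_series(days, sol$weight, "body_weight_g"),
       tumor_series = observation_series(days, sol$tumor, "tumor_mm3"),
       trajectory = sol$traj)
}

#' Generate a cachectic (untreated, tumor-bearing) cohort
#'
#' Solves the cachexia system from initial conditions derived from the
#' cohort's day-0 weight (via the reference stem ratio), then emits the
#' three observables the pipeline consumes: noiseless lean mass
#' `xi (S + M)`, noiseless tumor volume, and per-animal gross body weights
#' `lean / lean_fraction + xi T` with measurement noise. The weight
#' reconstruction inverts the lean-mass deconstruction, so at `cv = 0`
#' round-tripping through [weight_to_lean_compartments()] (with the
#' predicted tumor mass subtracted) recovers the lean series exactly.
#'
#' @param spec a [cohort_spec()] whose `params` carries `healthy`,
#'   `cachexia`, and `tumor` bundles (plus `treatment` for the treated
#'   generator).
#' @param day0_weight cohort average body weight on implantation day (g).
#' @param psi_ref reference stem ratio (defaults to the day-49 healthy
#'   ratio).
#' @param conv a [conversion_convention()].
#' @param T0 implantation volume (mm^3).
#' @return A list: `animals` (noisy per-animal weights), `lean_series`,
#'   `weight_series`, `tumor_series` (noiseless [observation_series()]),
#'   and the underlying `trajectory`.
#' @export
generate_cachexia_cohort <- function(spec, day0_weight,
                                     psi_ref = NULL,
                                     conv = conversion_convention(),
                                     T0 = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(psi_ref)) psi_ref <- reference_stem_ratio(spec$params$healthy)
  sol <- .cohort_solve(spec, day0_weight, psi_ref, conv, T0, treated = FALSE)
  .cohort_output(spec, sol)
}

#' Generate a treated (tumor-bearing) cohort
#'
#' As [generate_cachexia_cohort()], but the solve follows the piecewise
#' treatment protocol of `spec$params$treatment` (cachexia until
#' `t_start`, treated system after).
#'
#' @inheritParams generate_cachexia_cohort
#' @return Same structure as [generate_cachexia_cohort()].
#' @export
generate_treatment_cohort <- function(spec, day0_weight,
                                      psi_ref = NULL,
                                      conv = conversion_convention(),
                                      T0 = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"),
            inherits(spec$params$treatment, "treatment_params"))
  if (is.null(psi_ref)) psi_ref <- reference_stem_ratio(spec$params$healthy)
  sol <- .cohort_solve(spec, day0_weight, psi_ref, conv, T0, treated = TRUE)
  .cohort_output(spec, sol)
}

#' Write a generated cohort to disk
#'
#' Emits a long-format CSV (`animal_id`, `day`, `value`, `observable`) and
#' a JSON manifest recording the generating spec and seed.
#'
#' @param cohort output of one of the `generate_*_cohort()` functions.
#' @param spec the [cohort_spec()] that generated it.
#' @param dir output directory (created if missing).
#' @param stem file-name stem.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, spec, dir, stem = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(animal_id = cohort$animals$animal_id,
                     day = cohort$animals$day,
                     value = cohort$animals$weight_g,
                     observable = "body_weight_g")
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(long, csv, row.names = FALSE)
  manifest <- file.path(dir, paste0(stem, "_manifest.json"))
  jsonlite::write_json(list(n = spec$n, schedule = spec$schedule,
                            cv = spec$cv, seed = spec$seed),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, manifest = manifest))
}
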