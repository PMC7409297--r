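# Parameter containers for the muscle-wasting model family.
# All validation is eager (on construction) with named-inequality messages,
# because the feedback model is extremely sensitive near p = 1/2 and silent
# acceptance of an infeasible bundle would surface as a confusing blow-up
# deep inside the solver.

.check_num <- function(x, name, lower = -Inf, upper = Inf,
                       strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    lo <- if (strict_lower) "<" else "<="
    hi <- if (strict_upper) "<" else "<="
    stop(sprintf("`%s` must satisfy %s %s %s %s %s (got %g)",
                 name, format(lower), lo, name, hi, format(upper), x),
         call. = FALSE)
  }
  as.numeric(x)
}

#' Healthy muscle feedback parameters
#'
#' The homeostatic model tracks satellite cells `S` and muscle cells `M`.
#' Satellite-cell self-renewal probability and division rate are both
#' down-regulated by muscle mass through Hill-type negative feedback with a
#' common half-saturation volume `m`:
#' `p(M) = p0 + p1 / (1 + M/m)` and `nu(M) = nu0 + nu1 / (1 + M/m)`.
#'
#' @param p0 homeostatic self-renewal probability (dimensionless).
#' @param p1 perturbation self-renewal probability activated during growth or
#'   injury (dimensionless); `0 < p0 + p1 <= 1` is required so `p` stays a
#'   probability.
#' @param nu0 homeostatic division rate (per day).
#' @param nu1 perturbation division rate (per day).
#' @param d0 natural muscle-cell death rate (per day).
#' @param m feedback half-saturation volume (mm^3).
#'
#' @return An object of class `healthy_params`.
#' @seealso [fitted_params()] for the C26-mouse fitted values,
#'   [steady_state()] for the closed-form equilibrium.
#' @export
healthy_params <- function(p0, p1, nu0, nu1, d0, m) {
  p0  <- .check_num(p0, "p0", 0)
  p1  <- .check_num(p1, "p1", 0)
  nu0 <- .check_num(nu0, "nu0", 0)
  nu1 <- .check_num(nu1, "nu1", 0)
  d0  <- .check_num(d0, "d0", 0)
  m   <- .check_num(m, "m", 0, strict_lower = TRUE)
  if (!(p0 + p1 > 0 && p0 + p1 <= 1)) {
    stop(sprintf("self-renewal probabilities must satisfy 0 < p0 + p1 <= 1 (got p0 + p1 = %g)",
                 p0 + p1), call. = FALSE)
  }
  structure(list(p0 = p0, p1 = p1, nu0 = nu0, nu1 = nu1, d0 = d0, m = m),
            class = "healthy_params")
}

#' Assert that healthy parameters admit a positive steady state
#'
#' The closed-form equilibrium is positive only when `p0 < 1/2 < p0 + p1`.
#' Transients with `p(t) > 1/2` are normal during growth, so this check is
#' applied only by steady-state operations, never by the simulator.
#'
#' @param hp a [healthy_params()] object.
#' @return `hp`, invisibly.
#' @export
assert_homeostatic <- function(hp) {
  stopifnot(inherits(hp, "healthy_params"))
  if (!(hp$p0 < 0.5)) {
    stop(sprintf("steady state requires p0 < 1/2 (got p0 = %g)", hp$p0),
         call. = FALSE)
  }
  if (!(hp$p0 + hp$p1 > 0.5)) {
    stop(sprintf("steady state requires 1/2 < p0 + p1 (got p0 + p1 = %g)",
                 hp$p0 + hp$p1), call. = FALSE)
  }
  invisible(hp)
}

#' Exponential-linear tumor growth parameters
#'
#' Tumor volume grows exponentially at rate `mu` below the threshold
#' `Tth = mu1/mu` and linearly at `mu1` above it; `eta` sets how sharply the
#' two phases are blended into a single smooth ODE.
#'
#' @param mu exponential growth rate (per day), `> 0`.
#' @param mu1 linear growth rate (mm^3 per day), `> 0`.
#' @param eta transition sharpness (dimensionless, `>= 1`).
#' @return An object of class `tumor_params`.
#' @export
tumor_params <- function(mu, mu1, eta = 20) {
  mu  <- .check_num(mu, "mu", 0, strict_lower = TRUE)
  mu1 <- .check_num(mu1, "mu1", 0, strict_lower = TRUE)
  eta <- .check_num(eta, "eta", 1)
  structure(list(mu = mu, mu1 = mu1, eta = eta), class = "tumor_params")
}

#' Cachexia perturbation parameters
#'
#' Tumor-derived signalling perturbs the healthy system through a saturating
#' factor `T/(m2 + T)`: it suppresses satellite proliferation by at most
#' `eps`, and adds death rates `dS` (satellite) and `dM` (muscle).
#'
#' @param eps maximum proliferation suppression, in `[0, 1]`.
#' @param dS tumor-induced satellite-cell death rate (per day).
#' @param dM tumor-induced muscle-cell death rate (per day).
#' @param m2 tumor half-saturation volume (mm^3), `> 0`.
#' @return An object of class `cachexia_params`.
#' @export
cachexia_params <- function(eps, dS, dM, m2) {
  eps <- .check_num(eps, "eps", 0, 1)
  dS  <- .check_num(dS, "dS", 0)
  dM  <- .check_num(dM, "dM", 0)
  m2  <- .check_num(m2, "m2", 0, strict_lower = TRUE)
  structure(list(eps = eps, dS = dS, dM = dM, m2 = m2),
            class = "cachexia_params")
}

#' ActRIIB-blockade treatment parameters
#'
#' Efficacy multipliers `A1..A4` in `[0, 1]` scale, respectively, the
#' proliferation-suppression strength `eps`, the satellite death rate `dS`,
#' the tumor-induced muscle death rate `dM`, and the natural muscle death
#' rate `d0`. `Ai = 1` means no effect; `Ai = 0` removes the mechanism.
#'
#' @param A1,A2,A3,A4 efficacy multipliers in `[0, 1]`.
#' @param t_start day treatment begins (days since tumor implantation).
#' @return An object of class `treatment_params`.
#' @export
treatment_params <- function(A1, A2, A3, A4, t_start = 0) {
  A1 <- .check_num(A1, "A1", 0, 1)
  A2 <- .check_num(A2, "A2", 0, 1)
  A3 <- .check_num(A3, "A3", 0, 1)
  A4 <- .check_num(A4, "A4", 0, 1)
  t_start <- .check_num(t_start, "t_start", 0)
  structure(list(A1 = A1, A2 = A2, A3 = A3, A4 = A4, t_start = t_start),
            class = "treatment_params")
}

#' Logistic body-weight growth parameters
#'
#' @param alpha growth rate (per day), `> 0`.
#' @param K carrying capacity (g), `> 0`.
#' @param W0 body weight at day 0 (g), `0 < W0 <= K`.
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(alpha, K, W0) {
  alpha <- .check_num(alpha, "alpha", 0, strict_lower = TRUE)
  K     <- .check_num(K, "K", 0, strict_lower = TRUE)
  W0    <- .check_num(W0, "W0", 0, K, strict_lower = TRUE)
  structure(list(alpha = alpha, K = K, W0 = W0), class = "logistic_params")
}

#' Mass/volume conversion convention
#'
#' Body weight is deconstructed as 40% skeletal lean mass, split 95% muscle
#' and 5% satellite cells, and converted between grams and mm^3 with the
#' density-like factor `xi` (a 1000 mm^3 tumor weighing 2 g gives 0.002
#' g/mm^3).
#'
#' @param xi mass-per-volume factor (g per mm^3).
#' @param lean_fraction fraction of body weight that is skeletal lean mass.
#' @param muscle_share,stem_share split of lean mass between the muscle and
#'   satellite compartments; must sum to 1.
#' @return An object of class `conversion_convention`.
#' @export
conversion_convention <- function(xi = 0.002, lean_fraction = 0.40,
                                  muscle_share = 0.95, stem_share = 0.05) {
  xi <- .check_num(xi, "xi", 0, strict_lower = TRUE)
  lean_fraction <- .check_num(lean_fraction, "lean_fraction", 0, 1,
                              strict_lower = TRUE)
  muscle_share <- .check_num(muscle_share, "muscle_share", 0, 1)
  stem_share <- .check_num(stem_share, "stem_share", 0, 1)
  if (abs(muscle_share + stem_share - 1) > 1e-12) {
    stop("muscle_share + stem_share must equal 1", call. = FALSE)
  }
  structure(list(xi = xi, lean_fraction = lean_fraction,
                 muscle_share = muscle_share, stem_share = stem_share),
            class = "conversion_convention")
}

#' Instantaneous tissue state
#'
#' @param S satellite compartment volume (mm^3).
#' @param M muscle compartment volume (mm^3).
#' @param T tumor volume (mm^3); `NULL` for the healthy system.
#' @return An object of class `tissue_state`.
#' @export
tissue_state <- function(S, M, T = NULL) {
  S <- .check_num(S, "S", 0)
  M <- .check_num(M, "M", 0)
  if (!is.null(T)) T <- .check_num(T, "T", 0)
  structure(list(S = S, M = M, T = T), class = "tissue_state")
}

.param_class_for <- c(healthy = "healthy_params", tumor = "tumor_params",
                      cachexia = "cachexia_params",
                      treatment = "treatment_params",
                      logistic = "logistic_params",
                      conversion = "conversion_convention")

.param_ctor_for <- function(type) {
  switch(type,
         healthy = healthy_params, tumor = tumor_params,
         cachexia = cachexia_params, treatment = treatment_params,
         logistic = logistic_params, conversion = conversion_convention,
         stop(sprintf("unknown parameter type '%s'", type), call. = FALSE))
}

#' Read or write a parameter bundle as JSON or YAML
#'
#' Field names in the file match the constructor arguments exactly, so
#' bundles round-trip through either format.
#'
#' @param params a parameter object created by one of the constructors.
#' @param path file path ending in `.json`, `.yaml`, or `.yml`.
#' @param type one of `"healthy"`, `"tumor"`, `"cachexia"`, `"treatment"`,
#'   `"logistic"`, `"conversion"`.
#' @return `read_params()` returns the validated parameter object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path, type) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file '%s' does not exist", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop(sprintf("unsupported parameter file extension '.%s'", ext),
                     call. = FALSE))
  do.call(.param_ctor_for(type), as.list(raw))
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  x <- x[!vapply(x, is.null, logical(1))]
  switch(ext,
         json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
         yaml = ,
         yml = yaml::write_yaml(x, path),
         stop(sprintf("unsupported parameter file extension '.%s'", ext),
              call. = FALSE))
  invisible(path)
}

#' Fitted parameter bundles for the C26 mouse study
#'
#' Returns the parameter values obtained by calibrating the model family to
#' CDF1-mouse growth data and C26 tumor-bearing cohorts (with or without
#' soluble-ActRIIB treatment). These are shipped as plain-text fixtures under
#' `inst/extdata/` and validated on load.
#'
#' @param type which bundle: the healthy feedback constants, the
#'   exponential-linear tumor growth rates, the cachexia perturbation rates,
#'   the treatment efficacies fitted to the early-treatment cohort
#'   (`"treatment_a"`, treatment from day 5) or the late-treatment cohort
#'   (`"treatment_b"`, day 14), the logistic body-weight curve, or the
#'   mass/volume conversion convention.
#' @return The corresponding validated parameter object.
#' @export
fitted_params <- function(type = c("healthy", "tumor", "cachexia",
                                   "treatment_a", "treatment_b",
                                   "logistic", "conversion")) {
  type <- match.arg(type)
  file <- paste0(type, ".json")
  path <- system.file("extdata", file, package = "cachexim", mustWork = TRUE)
  base <- sub("_[ab]$", "", type)
  read_params(path, base)
}

#' Reference tissue states and cohort weights for the C26 study
#'
#' `healthy_initial_state("three_week")` (the default) is the day-0 state of
#' the healthy clock (age 3 weeks): the 40% lean-fraction deconstruction of
#' the 11.26 g average body weight, giving S = 112.6 and M = 2139.4 mm^3.
#' `healthy_initial_state("ten_week")` is the commonly quoted adult
#' reference state S = 268.01, M = 5088.92 mm^3; integrating the fitted
#' healthy model from the three-week state for 49 days reproduces this
#' state (and its ratio, the day-49 stem ratio 0.05266544) to the printed
#' precision, so the two recipes are two points on the same trajectory.
#' `cohort_day0_weight()` returns the average body weight on tumor
#' implantation day (healthy day 49) for the two experimental cohorts.
#'
#' @param age which reference state to return.
#' @return `healthy_initial_state()`: a [tissue_state()] in mm^3.
#' @export
healthy_initial_state <- function(age = c("three_week", "ten_week")) {
  age <- match.arg(age)
  if (age == "ten_week") {
    return(tissue_state(S = 268.01, M = 5088.92))
  }
  lean <- weight_to_lean_compartments(11.26)
  tissue_state(S = lean$stem_mm3, M = lean$muscle_mm3)
}

#' @rdname healthy_initial_state
#' @param group `"A"` (early-treatment cohort) or `"B"` (late-treatment).
#' @return `cohort_day0_weight()`: average day-0 body weight in grams.
#' @export
cohort_day0_weight <- function(group = c("A", "B")) {
  group <- match.arg(group)
  c(A = 25.26, B = 25.10)[[group]]
}

#' @export
print.healthy_params <- function(x, ...) {
  cat("Healthy muscle feedback parameters\n")
  cat(sprintf("  p0 = %g, p1 = %g (self-renewal)\n", x$p0, x$p1))
  cat(sprintf("  nu0 = %g, nu1 = %g per day (division)\n", x$nu0, x$nu1))
  cat(sprintf("  d0 = %g per day, m = %g mm^3\n", x$d0, x$m))
  invisible(x)
}

#' @export
print.tumor_params <- function(x, ...) {
  cat(sprintf("Exponential-linear tumor growth: mu = %g /day, mu1 = %g mm^3/day, eta = %g\n",
              x$mu, x$mu1, x$eta))
  cat(sprintf("  transition threshold mu1/mu = %g mm^3\n", x$mu1 / x$mu))
  invisible(x)
}
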