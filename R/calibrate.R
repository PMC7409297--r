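# Three-stage calibration pipeline: logistic extension of the body-weight
# data, simulated annealing for the healthy feedback constants, and
# exhaustive grid searches on the RMSE for the tumor, cachexia, and
# treatment parameters.

#' An observed time series
#'
#' @param days measurement days, non-decreasing.
#' @param values non-negative observations (grams for body weight / lean
#'   mass, mm^3 for tumor volume).
#' @param kind free-text observable label, e.g. `"body_weight_g"`,
#'   `"lean_mass_g"`, `"tumor_mm3"`.
#' @return An object of class `observation_series`.
#' @export
observation_series <- function(days, values, kind = "value") {
  days <- as.numeric(days); values <- as.numeric(values)
  if (length(days) != length(values)) {
    stop("days and values must have equal length", call. = FALSE)
  }
  if (length(days) > 1 && any(diff(days) < 0)) {
    stop("days must be non-decreasing", call. = FALSE)
  }
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  structure(list(days = days, values = values, kind = kind),
            class = "observation_series")
}

#' Root-mean-squared error
#'
#' `rmse()` compares two aligned series; `rmse_pooled()` concatenates the
#' residuals of several predicted/observed pairs before averaging, as done
#' for the healthy fit where muscle-mass and satellite-mass residuals enter
#' one objective.
#'
#' @param predicted,observed numeric vectors of equal length.
#' @return Non-negative scalar in the units of the observable.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' @rdname rmse
#' @param pairs a list of `list(predicted, observed)` pairs.
#' @export
rmse_pooled <- function(pairs) {
  res <- unlist(lapply(pairs, function(p) {
    if (length(p[[1]]) != length(p[[2]])) {
      stop("predicted and observed must have equal length", call. = FALSE)
    }
    p[[1]] - p[[2]]
  }))
  sqrt(mean(res^2))
}

#' Closed-form logistic body-weight curve
#'
#' @param t days since day 0; vectorised.
#' @param lp a [logistic_params()] object.
#' @return Body weight in grams.
#' @export
logistic_weight <- function(t, lp) {
  stopifnot(inherits(lp, "logistic_params"))
  e <- exp(lp$alpha * t)
  lp$K * lp$W0 * e / (lp$K + lp$W0 * (e - 1))
}

#' A calibration result
#'
#' Container returned by every `fit_*` function: the fitted parameter
#' bundle, the RMSE of the fit, the fixed (non-fitted) parameter record,
#' and optimizer diagnostics sufficient to re-run deterministically (seed
#' and objective trace for simulated annealing; the full objective surface
#' for grid searches).
#'
#' @param params fitted parameter object or named list.
#' @param rmse_value non-negative RMSE in the units of the observable.
#' @param diagnostics named list of optimizer diagnostics.
#' @param fixed named list of parameters held fixed during the fit.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(params, rmse_value, diagnostics = list(),
                       fixed = list()) {
  if (rmse_value < 0) stop("RMSE must be non-negative", call. = FALSE)
  structure(list(params = params, rmse = rmse_value,
                 diagnostics = diagnostics, fixed = fixed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (RMSE =", format(x$rmse), ")\n")
  p <- unclass(x$params)
  cat(paste0("  ", names(p), " = ", vapply(p, format, "")), sep = "\n")
  invisible(x)
}

#' Fit the logistic growth curve to body-weight data
#'
#' Nonlinear least squares (`minpack.lm::nlsLM`) on the closed-form
#' logistic solution. When a day-0 observation is present, `W0` is fixed to
#' it and only `alpha` and `K` are estimated. A constant series makes
#' `alpha` unidentifiable; in that case `K` is reported as the constant and
#' the result is flagged `alpha_unconstrained`.
#'
#' @param weights an [observation_series()] of body weights (g), at least 3
#'   points.
#' @return A [fit_result()] whose `params` is a [logistic_params()] (with
#'   `alpha = NA` in the degenerate case, returned as a plain list since a
#'   validated object requires a positive rate).
#' @export
fit_logistic <- function(weights) {
  stopifnot(inherits(weights, "observation_series"))
  d <- weights$days; w <- weights$values
  if (length(d) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (stats::sd(w) / mean(w) < 1e-10) {
    return(fit_result(list(alpha = NA_real_, K = mean(w), W0 = w[1]),
                      0, diagnostics = list(alpha_unconstrained = TRUE)))
  }
  fix_w0 <- any(d == 0)
  W0_fix <- if (fix_w0) w[d == 0][1] else NA
  Kmax <- max(w)
  start <- list(alpha = 0.05, K = Kmax * 1.05)
  if (!fix_w0) start$W0 <- w[1]
  model_fn <- function(alpha, K, W0) {
    e <- exp(alpha * d)
    K * W0 * e / (K + W0 * (e - 1))
  }
  fit <- tryCatch({
    if (fix_w0) {
      minpack.lm::nlsLM(w ~ model_fn(alpha, K, W0_fix),
                        start = start,
                        lower = c(1e-6, Kmax * 0.5),
                        upper = c(2, Kmax * 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(w ~ model_fn(alpha, K, W0),
                        start = start,
                        lower = c(1e-6, Kmax * 0.5, min(w) * 0.1),
                        upper = c(2, Kmax * 10, Kmax),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop(sprintf("logistic fit failed to converge: %s (starts: alpha=%g, K=%g)",
                 conditionMessage(e), start$alpha, start$K), call. = FALSE)
  })
  cf <- stats::coef(fit)
  lp <- logistic_params(alpha = cf[["alpha"]], K = cf[["K"]],
                        W0 = if (fix_w0) W0_fix else cf[["W0"]])
  fit_result(lp, rmse(stats::predict(fit), w),
             diagnostics = list(W0_fixed = fix_w0,
                                iterations = fit$convInfo$finIter),
             fixed = if (fix_w0) list(W0 = W0_fix) else list())
}

#' Extend an observed series with logistic-curve samples
#'
#' Appends samples of the fitted logistic curve on a fixed schedule (every
#' 10 days from day 90 to day 300 by default) past the last observed day,
#' so a fit to the extended dataset captures the homeostatic adult size
#' that the raw growth data do not reach.
#'
#' @param lp a [logistic_params()] object.
#' @param observed an [observation_series()] of body weights.
#' @param from,horizon,by the sampling schedule in days; only days after
#'   the last observed day are appended.
#' @return An [observation_series()] containing the observed points plus
#'   the appended samples.
#' @export
extend_dataset <- function(lp, observed, from = 90, horizon = 300, by = 10) {
  stopifnot(inherits(lp, "logistic_params"),
            inherits(observed, "observation_series"))
  last_day <- max(observed$days)
  new_days <- if (horizon >= from) seq(from, horizon, by = by) else numeric(0)
  new_days <- new_days[new_days > last_day]
  observation_series(c(observed$days, new_days),
                     c(observed$values, logistic_weight(new_days, lp)),
                     kind = observed$kind)
}

#' Simulated-annealing control settings
#'
#' Defaults: geometric cooling by a factor 0.95 across 200 temperatures
#' with 50 proposals each, Gaussian proposals scaled per parameter to a
#' tenth of its box, and reflection at the box boundaries.
#'
#' @param seed integer RNG seed; recorded in the diagnostics so any fit can
#'   be re-run bit-identically.
#' @param t0 initial temperature (objective units); `NULL` auto-scales to
#'   the objective value at the starting point.
#' @param cooling geometric cooling factor in (0, 1).
#' @param n_temps number of temperature levels.
#' @param n_props proposals per temperature.
#' @param step_frac initial proposal s.d. as a fraction of each parameter's
#'   box.
#' @param step_decay geometric shrink factor applied to the proposal s.d.
#'   at each temperature level (floored at 1e-4 of the box), so the walk
#'   explores early and refines late.
#' @param polish if `TRUE`, finish with a deterministic derivative-free
#'   local search (Nelder-Mead) from the annealed optimum. The feedback
#'   objective has a narrow curved valley that isotropic Gaussian steps
#'   descend very slowly; annealing locates the valley and the polish walks
#'   it to the bottom.
#' @return A list of class `sa_control`.
#' @export
sa_control <- function(seed = 1L, t0 = NULL, cooling = 0.95,
                       n_temps = 200L, n_props = 50L, step_frac = 0.1,
                       step_decay = 0.95, polish = TRUE) {
  stopifnot(cooling > 0, cooling < 1, n_temps >= 1, n_props >= 1,
            step_frac > 0, step_decay > 0, step_decay <= 1)
  structure(list(seed = as.integer(seed), t0 = t0, cooling = cooling,
                 n_temps = as.integer(n_temps), n_props = as.integer(n_props),
                 step_frac = step_frac, step_decay = step_decay,
                 polish = isTRUE(polish)),
            class = "sa_control")
}

.reflect <- function(x, lower, upper) {
  # fold proposals back into the box; loop handles large excursions
  span <- upper - lower
  for (i in seq_along(x)) {
    while (x[i] < lower[i] || x[i] > upper[i]) {
      if (x[i] < lower[i]) x[i] <- 2 * lower[i] - x[i]
      if (x[i] > upper[i]) x[i] <- 2 * upper[i] - x[i]
    }
  }
  x
}

#' Minimize an objective by simulated annealing
#'
#' Bounded simulated annealing with reflective Gaussian proposals and a
#' geometric cooling schedule. Infeasible points may be signalled by the
#' objective returning `Inf`; if every proposal is infeasible the run
#' errors.
#'
#' @param objective function of a named numeric vector, returning a scalar
#'   (may be `Inf` for infeasible points).
#' @param lower,upper named numeric bounds defining the search box.
#' @param init starting point; defaults to the box centre.
#' @param control an [sa_control()].
#' @return A list with `par` (best point), `value` (best objective),
#'   `trace` (best objective per temperature), `accepted` (acceptance count
#'   per temperature), and `seed`.
#' @export
sa_minimize <- function(objective, lower, upper, init = NULL,
                        control = sa_control()) {
  stopifnot(length(lower) == length(upper), all(upper > lower))
  if (is.null(init)) init <- (lower + upper) / 2
  set.seed(control$seed)
  cur <- init
  f_cur <- objective(cur)
  if (!is.finite(f_cur)) {
    # pull a feasible start from the box
    for (k in 1:100) {
      cur <- lower + stats::runif(length(lower)) * (upper - lower)
      f_cur <- objective(cur)
      if (is.finite(f_cur)) break
    }
    if (!is.finite(f_cur)) {
      stop("no feasible starting point found in the search box", call. = FALSE)
    }
  }
  best <- cur; f_best <- f_cur
  temp <- if (is.null(control$t0)) max(abs(f_cur), 1e-8) else control$t0
  sd_prop <- control$step_frac * (upper - lower)
  trace <- numeric(control$n_temps)
  accepted <- integer(control$n_temps)
  n_feasible <- 0L
  for (i in seq_len(control$n_temps)) {
    for (j in seq_len(control$n_props)) {
      prop <- .reflect(cur + stats::rnorm(length(cur), 0, sd_prop),
                       lower, upper)
      f_prop <- objective(prop)
      if (is.finite(f_prop)) n_feasible <- n_feasible + 1L
      if (is.finite(f_prop) &&
          (f_prop <= f_cur ||
           stats::runif(1) < exp(-(f_prop - f_cur) / temp))) {
        cur <- prop; f_cur <- f_prop
        accepted[i] <- accepted[i] + 1L
        if (f_cur < f_best) { best <- cur; f_best <- f_cur }
      }
    }
    trace[i] <- f_best
    temp <- temp * control$cooling
    sd_prop <- pmax(sd_prop * control$step_decay,
                    1e-4 * (upper - lower))
    # restart each temperature from the incumbent best so late, small
    # steps polish the best basin rather than a stray walker
    if (f_cur > f_best) { cur <- best; f_cur <- f_best }
  }
  if (n_feasible == 0L) {
    stop("all simulated-annealing proposals were infeasible", call. = FALSE)
  }
  if (control$polish) {
    pen <- function(x) {
      x <- .reflect(x, lower, upper)
      v <- objective(x)
      if (is.finite(v)) v else 1e10
    }
    loc <- stats::optim(best, pen, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    cand <- .reflect(loc$par, lower, upper)
    f_cand <- objective(cand)
    if (is.finite(f_cand) && f_cand < f_best) {
      best <- cand; f_best <- f_cand
    }
  }
  list(par = best, value = f_best, trace = trace, accepted = accepted,
       seed = control$seed)
}

.healthy_pred <- function(p, d0, m, state0, days, conv) {
  hp <- tryCatch(healthy_params(p[["p0"]], p[["p1"]], p[["nu0"]], p[["nu1"]],
                                d0, m),
                 error = function(e) NULL)
  if (is.null(hp)) return(NULL)
  if (!(hp$p0 < 0.5 && hp$p0 + hp$p1 > 0.5)) return(NULL)
  times <- sort(unique(c(0, days)))
  spec <- experiment_spec("healthy", list(healthy = hp), state0, times,
                          rtol = 1e-8, atol = 1e-10)
  traj <- tryCatch(integrate_model(spec), error = function(e) NULL)
  if (is.null(traj)) return(NULL)
  idx <- match(days, traj$times)
  list(muscle_g = conv$xi * traj$M[idx], stem_g = conv$xi * traj$S[idx])
}

#' Fit the healthy feedback parameters by simulated annealing
#'
#' Hierarchical scheme: the death rate `d0` and half-saturation volume `m`
#' are held fixed while simulated annealing fits `(p0, p1, nu0, nu1)` to
#' the pooled muscle-mass and satellite-mass residuals (in grams,
#' unweighted by default); an outer loop repeats the fit over a small grid
#' of `(d0, m)` candidates and returns the global best.
#'
#' @param muscle,stem [observation_series()] of muscle and satellite mass
#'   (g) on common days (typically from [weight_to_lean_compartments()]).
#' @param d0,m candidate values (vectors allowed) for the fixed parameters.
#' @param control an [sa_control()]; the seed is recorded in diagnostics.
#' @param conv a [conversion_convention()].
#' @param stem_weight multiplier on the stem residuals (the stem series is
#'   about 19x smaller than the muscle series; 1 reproduces the unweighted
#'   pooling).
#' @param bounds named list of `c(lower, upper)` boxes for the four fitted
#'   parameters.
#' @return A [fit_result()] with a [healthy_params()] bundle, the pooled
#'   RMSE (g), and diagnostics (`seed`, objective `trace`, `d0_m_grid`).
#' @export
fit_healthy <- function(muscle, stem, d0 = 0.05, m = 1000,
                        control = sa_control(), conv = conversion_convention(),
                        stem_weight = 1,
                        bounds = list(p0 = c(0.30, 0.4999),
                                      p1 = c(0.005, 0.6),
                                      nu0 = c(0.005, 1),
                                      nu1 = c(0.1, 10))) {
  stopifnot(inherits(muscle, "observation_series"),
            inherits(stem, "observation_series"))
  if (length(muscle$days) == 0 || length(stem$days) == 0) {
    stop("empty observation series", call. = FALSE)
  }
  if (!identical(muscle$days, stem$days)) {
    stop("muscle and stem series must share measurement days", call. = FALSE)
  }
  if (!any(muscle$days == 0)) {
    stop("a day-0 observation is required to set initial conditions",
         call. = FALSE)
  }
  state0 <- tissue_state(S = stem$values[stem$days == 0][1] / conv$xi,
                         M = muscle$values[muscle$days == 0][1] / conv$xi)
  lower <- vapply(bounds, `[`, 0, 1)
  upper <- vapply(bounds, `[`, 0, 2)
  names(lower) <- names(upper) <- names(bounds)
  best <- NULL
  grid <- expand.grid(d0 = d0, m = m)
  for (g in seq_len(nrow(grid))) {
    obj <- function(p) {
      names(p) <- names(bounds)
      pred <- .healthy_pred(p, grid$d0[g], grid$m[g], state0, muscle$days, conv)
      if (is.null(pred)) return(Inf)
      rmse_pooled(list(list(pred$muscle_g, muscle$values),
                       list(stem_weight * pred$stem_g,
                            stem_weight * stem$values)))
    }
    res <- sa_minimize(obj, lower, upper, control = control)
    if (is.null(best) || res$value < best$res$value) {
      best <- list(res = res, d0 = grid$d0[g], m = grid$m[g])
    }
  }
  par <- best$res$par
  names(par) <- names(bounds)
  hp <- healthy_params(par[["p0"]], par[["p1"]], par[["nu0"]], par[["nu1"]],
                       best$d0, best$m)
  fit_result(hp, best$res$value,
             diagnostics = list(seed = best$res$seed,
                                trace = best$res$trace,
                                accepted = best$res$accepted,
                                d0_m_grid = grid),
             fixed = list(d0 = best$d0, m = best$m))
}

.grid_argmin <- function(surface) {
  idx <- which(surface == min(surface), arr.ind = TRUE)
  if (is.matrix(idx)) idx[1, , drop = TRUE] else idx[1]
}

#' Fit tumor growth rates by exhaustive grid search
#'
#' Solves the exponential-linear growth ODE from the implantation volume
#' for every `(mu, mu1)` pair on the grid and returns the RMSE argmin along
#' with the full objective surface.
#'
#' @param data an [observation_series()] of tumor volumes (mm^3).
#' @param mu_grid,mu1_grid candidate values. The documented "generous"
#'   defaults (`mu` 0.05-1.0 by 0.002, `mu1` 10-300 by 0.5) are expensive;
#'   pass coarser grids for exploratory work.
#' @param eta transition sharpness, fixed.
#' @param T0 implantation volume (mm^3), fixed.
#' @return A [fit_result()] with a [tumor_params()] bundle; diagnostics
#'   carry the objective `surface` (a `mu x mu1` matrix) and an
#'   `on_boundary` flag.
#' @export
fit_tumor <- function(data,
                      mu_grid = seq(0.05, 1.0, by = 0.002),
                      mu1_grid = seq(10, 300, by = 0.5),
                      eta = 20, T0 = 0.5) {
  stopifnot(inherits(data, "observation_series"))
  if (length(mu_grid) == 0 || length(mu1_grid) == 0) {
    stop("empty parameter grid", call. = FALSE)
  }
  times <- sort(unique(c(0, data$days)))
  surface <- matrix(NA_real_, length(mu_grid), length(mu1_grid),
                    dimnames = list(mu = NULL, mu1 = NULL))
  for (i in seq_along(mu_grid)) {
    for (j in seq_along(mu1_grid)) {
      tp <- tumor_params(mu_grid[i], mu1_grid[j], eta)
      out <- .solve_ode(c(T = T0), times,
                        function(t, y, parms) list(tumor_rate(y, tp)),
                        rtol = 1e-8, atol = 1e-10)
      pred <- out[match(data$days, out[, 1]), "T"]
      surface[i, j] <- rmse(pred, data$values)
    }
  }
  idx <- .grid_argmin(surface)
  i <- idx[1]; j <- if (length(idx) > 1) idx[2] else 1
  on_boundary <- i %in% c(1L, length(mu_grid)) && length(mu_grid) > 1 ||
    j %in% c(1L, length(mu1_grid)) && length(mu1_grid) > 1
  fit_result(tumor_params(mu_grid[i], mu1_grid[j], eta),
             surface[i, j],
             diagnostics = list(surface = surface, mu_grid = mu_grid,
                                mu1_grid = mu1_grid,
                                on_boundary = on_boundary),
             fixed = list(eta = eta, T0 = T0))
}

.lean_pred <- function(hp, cp, tp, tx, state0, days, conv, t_start = NULL) {
  times <- sort(unique(c(0, days)))
  params <- list(healthy = hp, cachexia = cp, tumor = tp)
  spec <- experiment_spec("cachexia", params, state0, times,
                          rtol = 1e-8, atol = 1e-10)
  traj <- if (is.null(tx)) integrate_model(spec) else
    simulate_treatment(spec, tx)
  idx <- match(days, traj$times)
  conv$xi * (traj$S[idx] + traj$M[idx])
}

#' Fit cachexia parameters by exhaustive grid search
#'
#' Fits the model-predicted lean mass `xi (S + M)` to observed lean-mass
#' data over a 4-dimensional grid on `(eps, dS, dM, m2)`, holding the
#' healthy and tumor parameters fixed. Initial compartment volumes come
#' from [initial_conditions_from_weight()] applied to the cohort's day-0
#' weight. The full objective surface is retained so the documented
#' flatness of the fit in `eps` can be inspected.
#'
#' @param data an [observation_series()] of lean mass (g).
#' @param grids named list of candidate vectors for `eps`, `dS`, `dM`,
#'   `m2`.
#' @param hp,tp fixed healthy and tumor parameter objects.
#' @param day0_weight cohort average body weight on implantation day (g).
#' @param psi_ref reference stem ratio for the initial split (defaults to
#'   the day-49 ratio of the healthy reference solve).
#' @param conv a [conversion_convention()].
#' @param T0 implantation volume (mm^3).
#' @return A [fit_result()] with a [cachexia_params()] bundle; diagnostics
#'   carry the objective surface (4-d array) and an `on_boundary` flag.
#' @export
fit_cachexia <- function(data, grids, hp, tp, day0_weight,
                         psi_ref = NULL, conv = conversion_convention(),
                         T0 = 0.5) {
  stopifnot(inherits(data, "observation_series"))
  need <- c("eps", "dS", "dM", "m2")
  if (!all(need %in% names(grids)) || any(lengths(grids[need]) == 0)) {
    stop("grids must supply non-empty eps, dS, dM, m2", call. = FALSE)
  }
  if (is.null(psi_ref)) psi_ref <- reference_stem_ratio(hp)
  ic <- initial_conditions_from_weight(day0_weight, psi_ref, conv)
  state0 <- tissue_state(S = ic[["S"]], M = ic[["M"]], T = T0)
  dims <- lengths(grids[need])
  surface <- array(NA_real_, dims, dimnames = stats::setNames(
    lapply(grids[need], as.character), need))
  for (i1 in seq_along(grids$eps)) for (i2 in seq_along(grids$dS))
    for (i3 in seq_along(grids$dM)) for (i4 in seq_along(grids$m2)) {
      cp <- cachexia_params(grids$eps[i1], grids$dS[i2], grids$dM[i3],
                            grids$m2[i4])
      pred <- .lean_pred(hp, cp, tp, NULL, state0, data$days, conv)
      surface[i1, i2, i3, i4] <- rmse(pred, data$values)
    }
  idx <- .grid_argmin(surface)
  if (length(idx) == 1) idx <- rep(1L, 4)  # scalar grid
  on_boundary <- any(mapply(function(k, n) n > 1 && (k == 1L || k == n),
                            idx, dims))
  cp <- cachexia_params(grids$eps[idx[1]], grids$dS[idx[2]],
                        grids$dM[idx[3]], grids$m2[idx[4]])
  fit_result(cp, surface[matrix(idx, 1)],
             diagnostics = list(surface = surface, grids = grids[need],
                                argmin_index = idx,
                                on_boundary = on_boundary),
             fixed = list(healthy = hp, tumor = tp, T0 = T0,
                          day0_weight = day0_weight, psi_ref = psi_ref))
}

#' Fit treatment efficacies by exhaustive grid search
#'
#' Grid argmin over `(A1, A2, A3, A4)` in `[0, 1]` using the piecewise
#' treatment protocol (cachexia until `t_start`, treated system after),
#' with all upstream healthy/cachexia/tumor parameters fixed.
#'
#' @param data an [observation_series()] of lean mass (g).
#' @param t_start treatment start day.
#' @param grids named list of candidate vectors for `A1`, `A2`, `A3`, `A4`.
#' @param hp,cp,tp fixed parameter objects.
#' @inheritParams fit_cachexia
#' @return A [fit_result()] with a [treatment_params()] bundle.
#' @export
fit_treatment <- function(data, t_start, grids, hp, cp, tp, day0_weight,
                          psi_ref = NULL, conv = conversion_convention(),
                          T0 = 0.5) {
  stopifnot(inherits(data, "observation_series"))
  need <- c("A1", "A2", "A3", "A4")
  if (!all(need %in% names(grids)) || any(lengths(grids[need]) == 0)) {
    stop("grids must supply non-empty A1, A2, A3, A4", call. = FALSE)
  }
  if (any(unlist(grids[need]) < 0) || any(unlist(grids[need]) > 1)) {
    stop("treatment efficacies must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(psi_ref)) psi_ref <- reference_stem_ratio(hp)
  ic <- initial_conditions_from_weight(day0_weight, psi_ref, conv)
  state0 <- tissue_state(S = ic[["S"]], M = ic[["M"]], T = T0)
  dims <- lengths(grids[need])
  surface <- array(NA_real_, dims)
  for (i1 in seq_along(grids$A1)) for (i2 in seq_along(grids$A2))
    for (i3 in seq_along(grids$A3)) for (i4 in seq_along(grids$A4)) {
      tx <- treatment_params(grids$A1[i1], grids$A2[i2], grids$A3[i3],
                             grids$A4[i4], t_start = t_start)
      pred <- .lean_pred(hp, cp, tp, tx, state0, data$days, conv)
      surface[i1, i2, i3, i4] <- rmse(pred, data$values)
    }
  idx <- .grid_argmin(surface)
  if (length(idx) == 1) idx <- rep(1L, 4)
  tx <- treatment_params(grids$A1[idx[1]], grids$A2[idx[2]],
                         grids$A3[idx[3]], grids$A4[idx[4]],
                         t_start = t_start)
  fit_result(tx, surface[matrix(idx, 1)],
             diagnostics = list(surface = surface, grids = grids[need],
                                argmin_index = idx),
             fixed = list(healthy = hp, cachexia = cp, tumor = tp,
                          T0 = T0, day0_weight = day0_weight,
                          psi_ref = psi_ref))
}
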