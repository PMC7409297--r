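# Local one-at-a-time sensitivity analysis: relative percent change of an
# observable under a +/-5% perturbation of one parameter, evaluated either
# at the closed-form healthy steady state or at day 20 of the
# cachexia/treatment solves.

#' Relative sensitivity of an observable to one parameter
#'
#' Computes `100 * (y(rho * (1 + f)) - y(rho)) / y(rho)` where `rho` is the
#' named parameter and `y` the observable.
#'
#' @param observable function taking a parameter list and returning a
#'   scalar.
#' @param params named list (or parameter object) of base values.
#' @param name parameter to perturb.
#' @param fraction signed perturbation fraction (e.g. `-0.05` for a 5%
#'   decrease).
#' @return Percent change (scalar).
#' @export
relative_sensitivity <- function(observable, params, name, fraction) {
  base_params <- as.list(unclass(params))
  if (!name %in% names(base_params)) {
    stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
  }
  y0 <- observable(base_params)
  if (!is.finite(y0) || y0 == 0) {
    stop("observable is zero or non-finite at the base point", call. = FALSE)
  }
  pert <- base_params
  pert[[name]] <- pert[[name]] * (1 + fraction)
  100 * (observable(pert) - y0) / y0
}

.ss_unchecked <- function(p) {
  # closed forms evaluated without the p0 < 1/2 guard, so perturbations
  # that cross into the unphysical regime still return the algebraic value
  Mss <- p$m * (2 * (p$p0 + p$p1) - 1) / (1 - 2 * p$p0)
  Sss <- 2 * p$m * p$d0 * p$p1 * (2 * (p$p0 + p$p1) - 1) /
    ((1 - 2 * p$p0) * (2 * p$p1 * p$nu0 + (1 - 2 * p$p0) * p$nu1))
  c(S = Sss, M = Mss)
}

#' Steady-state sensitivity table for the healthy model
#'
#' Perturbs each of `m`, `p0`, `p1`, `nu0`, `nu1`, `d0` by `+/-fraction`
#' and reports the percent change in the closed-form `Sss` and `Mss`.
#' Structural independence (e.g. `Mss` does not contain `nu0`, `nu1`, or
#' `d0`) is detected from the closed form itself — an exactly zero change —
#' and reported as `NA` rather than 0. Perturbations that push `p0` across
#' the 1/2 boundary are still evaluated algebraically but flagged
#' `unphysical`, since the perturbed "steady state" is negative there; the
#' extreme `p0` entries this produces are a documented feature of the
#' model's sensitivity near `p = 1/2`.
#'
#' @param hp a [healthy_params()] object admitting a steady state.
#' @param fraction perturbation size (default 0.05 for 5%).
#' @return A data frame with one row per parameter: `parameter`, `base`,
#'   `S_dec`, `S_inc`, `M_dec`, `M_inc` (percent changes under decrease /
#'   increase), and logical `unphysical_dec`, `unphysical_inc`.
#' @export
healthy_sensitivity_table <- function(hp, fraction = 0.05) {
  assert_homeostatic(hp)
  base <- as.list(unclass(hp))
  y0 <- .ss_unchecked(base)
  pars <- c("m", "p0", "p1", "nu0", "nu1", "d0")
  one_cell <- function(name, f, comp) {
    pert <- base
    pert[[name]] <- pert[[name]] * (1 + f)
    y <- .ss_unchecked(pert)
    delta <- 100 * (y[[comp]] - y0[[comp]]) / y0[[comp]]
    if (delta == 0) NA_real_ else delta
  }
  unphys <- function(name, f) {
    pert <- base
    pert[[name]] <- pert[[name]] * (1 + f)
    !(pert$p0 < 0.5 && pert$p0 + pert$p1 > 0.5 && pert$p0 + pert$p1 <= 1)
  }
  data.frame(
    parameter = pars,
    base = vapply(pars, function(p) base[[p]], 0),
    S_dec = vapply(pars, one_cell, 0, f = -fraction, comp = "S"),
    S_inc = vapply(pars, one_cell, 0, f = fraction, comp = "S"),
    M_dec = vapply(pars, one_cell, 0, f = -fraction, comp = "M"),
    M_inc = vapply(pars, one_cell, 0, f = fraction, comp = "M"),
    unphysical_dec = vapply(pars, unphys, TRUE, f = -fraction),
    unphysical_inc = vapply(pars, unphys, TRUE, f = fraction),
    row.names = NULL
  )
}

.day_eval <- function(hp, cp, tp, tx, state0, day, rtol, atol) {
  times <- c(0, day / 2, day)
  params <- list(healthy = hp, cachexia = cp, tumor = tp)
  spec <- experiment_spec("cachexia", params, state0, times,
                          rtol = rtol, atol = atol)
  traj <- if (is.null(tx)) integrate_model(spec) else
    simulate_treatment(spec, tx)
  n <- length(traj$times)
  c(S = traj$S[n], M = traj$M[n])
}

#' Day-20 sensitivity table for the cachexia and treatment models
#'
#' Perturbs each cachexia parameter (`m2`, `eps`, `dS`, `dM`) — and, when
#' `tx` is supplied, each treatment efficacy (`A3`, `A4`) with the
#' perturbation applied on top of the piecewise treatment protocol — by
#' `+/-fraction`, re-solves to the evaluation day, and reports the percent
#' change in `S(day)` and `M(day)`. The evaluation day defaults to day 20
#' post-implantation, inside the dynamic wasting phase.
#'
#' @param hp,cp,tp base parameter objects.
#' @param tx optional [treatment_params()]; when given, rows for `A3` and
#'   `A4` are appended (`A1`, `A2` are omitted since their fitted values
#'   are zero and a multiplicative perturbation of zero is still zero).
#' @param state0 initial [tissue_state()]; defaults to the early-treatment
#'   cohort's implantation state with a 0.5 mm^3 implant.
#' @param day evaluation day.
#' @param fraction perturbation size.
#' @param rtol,atol solver tolerances.
#' @return A data frame shaped like [healthy_sensitivity_table()], with a
#'   `model` column distinguishing cachexia and treatment rows.
#' @export
cachexia_sensitivity_table <- function(hp, cp, tp, tx = NULL, state0 = NULL,
                                       day = 20, fraction = 0.05,
                                       rtol = 1e-10, atol = 1e-12) {
  if (is.null(state0)) {
    state0 <- tissue_state(S = 252.75, M = 4799.25, T = 0.5)
  }
  rows <- list()
  base_cp <- as.list(unclass(cp))
  # cachexia rows are perturbations of the untreated solve; treatment rows
  # perturb the treated (piecewise) solve around its own base
  y0_cach <- .day_eval(hp, cp, tp, NULL, state0, day, rtol, atol)
  y0 <- y0_cach
  cell <- function(make_params, f) {
    y <- do.call(.day_eval, c(make_params(f),
                              list(state0 = state0, day = day,
                                   rtol = rtol, atol = atol)))
    100 * (y - y0) / y0
  }
  for (par in c("m2", "eps", "dS", "dM")) {
    mk <- function(f) {
      p <- base_cp; p[[par]] <- p[[par]] * (1 + f)
      list(hp = hp, cp = do.call(cachexia_params, p), tp = tp, tx = NULL)
    }
    dec <- cell(mk, -fraction); inc <- cell(mk, fraction)
    rows[[par]] <- data.frame(model = "cachexia", parameter = par,
                              base = base_cp[[par]],
                              S_dec = dec[["S"]], S_inc = inc[["S"]],
                              M_dec = dec[["M"]], M_inc = inc[["M"]])
  }
  if (!is.null(tx)) {
    base_tx <- as.list(unclass(tx))
    y0 <- .day_eval(hp, cp, tp, tx, state0, day, rtol, atol)
    for (par in c("A3", "A4")) {
      mk <- function(f) {
        p <- base_tx; p[[par]] <- p[[par]] * (1 + f)
        list(hp = hp, cp = cp, tp = tp, tx = do.call(treatment_params, p))
      }
      dec <- cell(mk, -fraction); inc <- cell(mk, fraction)
      rows[[par]] <- data.frame(model = "treatment", parameter = par,
                                base = base_tx[[par]],
                                S_dec = dec[["S"]], S_inc = inc[["S"]],
                                M_dec = dec[["M"]], M_inc = inc[["M"]])
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
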