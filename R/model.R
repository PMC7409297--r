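# Right-hand sides and closed-form algebra of the three ODE systems.
# State is always carried internally in volume units (mm^3); grams appear
# only at I/O boundaries through a `conversion_convention`.

#' Feedback-regulated self-renewal probability and division rate
#'
#' Both feedback laws share the Hill form `x0 + x1 / (1 + M/m)`: maximal at
#' `M = 0`, halved relative to the perturbation part at `M = m`, and decaying
#' to the homeostatic constant as muscle mass grows.
#'
#' @param M muscle compartment volume (mm^3), `>= 0`; vectorised.
#' @param hp a [healthy_params()] object.
#' @return `feedback_probability()`: the self-renewal probability
#'   `p0 + p1/(1 + M/m)`, in `(p0, p0 + p1]`.
#' @export
feedback_probability <- function(M, hp) {
  stopifnot(inherits(hp, "healthy_params"))
  if (any(M < 0)) stop("muscle volume M must be non-negative", call. = FALSE)
  hp$p0 + hp$p1 / (1 + M / hp$m)
}

#' @rdname feedback_probability
#' @return `feedback_division_rate()`: the division rate
#'   `nu0 + nu1/(1 + M/m)` in per day, in `(nu0, nu0 + nu1]`.
#' @export
feedback_division_rate <- function(M, hp) {
  stopifnot(inherits(hp, "healthy_params"))
  if (any(M < 0)) stop("muscle volume M must be non-negative", call. = FALSE)
  hp$nu0 + hp$nu1 / (1 + M / hp$m)
}

#' Healthy-model growth rates
#'
#' Symmetric lineage bookkeeping: an activated satellite cell divides into
#' two satellite cells with probability `p` (net stem gain `(2p-1) nu S`) or
#' two muscle cells with probability `1-p` (muscle gain `2(1-p) nu S`),
#' while muscle dies at the natural rate `d0`.
#'
#' @param state a [tissue_state()] without a tumor component (or a numeric
#'   `c(S, M)`).
#' @param hp a [healthy_params()] object.
#' @return Named numeric `c(dS, dM)` in mm^3 per day.
#' @export
healthy_rates <- function(state, hp) {
  if (inherits(state, "tissue_state")) {
    if (!is.null(state$T)) {
      stop("healthy_rates() takes a tumor-free state", call. = FALSE)
    }
    S <- state$S; M <- state$M
  } else {
    S <- state[[1]]; M <- state[[2]]
  }
  p <- feedback_probability(M, hp)
  nu <- feedback_division_rate(M, hp)
  c(dS = (2 * p - 1) * nu * S,
    dM = 2 * (1 - p) * nu * S - hp$d0 * M)
}

#' Exponential-linear tumor growth rate
#'
#' `dT/dt = mu T (1 + (mu T / mu1)^eta)^(-1/eta)`: exponential at rate `mu`
#' for small tumors, saturating to the constant `mu1` above the transition
#' threshold `Tth = mu1/mu`. Evaluated in log space so very large `T` does
#' not overflow the `eta`-th power.
#'
#' @param T tumor volume (mm^3), `>= 0`; vectorised.
#' @param tp a [tumor_params()] object.
#' @return Growth rate in mm^3 per day.
#' @export
tumor_rate <- function(T, tp) {
  stopifnot(inherits(tp, "tumor_params"))
  if (any(T < 0)) stop("tumor volume T must be non-negative", call. = FALSE)
  r <- tp$mu * T / tp$mu1
  out <- numeric(length(T))
  small <- r <= 1
  # (1 + r^eta)^(-1/eta); for r > 1 factor out r to keep r^eta bounded
  out[small] <- tp$mu * T[small] *
    exp(-log1p(r[small]^tp$eta) / tp$eta)
  if (any(!small)) {
    rl <- r[!small]
    out[!small] <- tp$mu1 * exp(-log1p(rl^(-tp$eta)) / tp$eta)
  }
  out
}

#' Transition threshold of the exponential-linear model
#'
#' The volume `Tth = mu1/mu` at which the exponential and linear growth
#' rates coincide; always recomputed from the rates, never stored.
#'
#' @param tp a [tumor_params()] object.
#' @return Threshold volume in mm^3.
#' @export
transition_threshold <- function(tp) {
  stopifnot(inherits(tp, "tumor_params"))
  tp$mu1 / tp$mu
}

#' Tumor-induced proliferation suppression factor
#'
#' `1 - eps * T/(m2 + T)`, the multiplicative reduction of satellite-cell
#' division caused by tumor-derived myostatin/activin-A signalling; ranges
#' from 1 (no tumor) down to `1 - eps` (large tumor).
#'
#' @param T tumor volume (mm^3), `>= 0`; vectorised.
#' @param cp a [cachexia_params()] object.
#' @return Dimensionless factor in `[1 - eps, 1]`.
#' @export
suppression_factor <- function(T, cp) {
  stopifnot(inherits(cp, "cachexia_params"))
  if (any(T < 0)) stop("tumor volume T must be non-negative", call. = FALSE)
  1 - cp$eps * T / (cp$m2 + T)
}

#' Cachexia-model growth rates
#'
#' The healthy system perturbed by a growing tumor: proliferation is scaled
#' by [suppression_factor()], and saturating tumor-induced death terms
#' `dS T/(m2+T) S` and `dM T/(m2+T) M` are added. The self-renewal
#' probability `p` is assumed unchanged by the tumor. Setting
#' `eps = dS = dM = 0` recovers [healthy_rates()] plus [tumor_rate()]
#' exactly.
#'
#' @param state a [tissue_state()] with tumor component, or numeric
#'   `c(S, M, T)`.
#' @param hp,cp,tp healthy, cachexia, and tumor parameter objects.
#' @return Named numeric `c(dS, dM, dT)` in mm^3 per day.
#' @export
cachexia_rates <- function(state, hp, cp, tp) {
  if (inherits(state, "tissue_state")) {
    if (is.null(state$T)) stop("cachexia_rates() needs a tumor component",
                               call. = FALSE)
    S <- state$S; M <- state$M; T <- state$T
  } else {
    S <- state[[1]]; M <- state[[2]]; T <- state[[3]]
  }
  p <- feedback_probability(M, hp)
  nu <- feedback_division_rate(M, hp)
  supp <- suppression_factor(T, cp)
  sat <- T / (cp$m2 + T)
  c(dS = (2 * p - 1) * nu * supp * S - cp$dS * sat * S,
    dM = 2 * (1 - p) * nu * supp * S - (hp$d0 + cp$dM * sat) * M,
    dT = tumor_rate(T, tp))
}

#' Treatment-model growth rates
#'
#' ActRIIB blockade scales each cachectic mechanism by an efficacy
#' multiplier: `A1` on the proliferation suppression `eps`, `A2` on the
#' satellite death rate `dS`, `A3` on the tumor-induced muscle death rate
#' `dM`, and `A4` on the natural muscle death rate `d0`. Tumor growth
#' itself is unaffected by treatment. With all `Ai = 1` this is identical
#' to [cachexia_rates()].
#'
#' @inheritParams cachexia_rates
#' @param tx a [treatment_params()] object.
#' @return Named numeric `c(dS, dM, dT)` in mm^3 per day.
#' @export
treatment_rates <- function(state, hp, cp, tp, tx) {
  stopifnot(inherits(tx, "treatment_params"))
  if (inherits(state, "tissue_state")) {
    S <- state$S; M <- state$M; T <- state$T
  } else {
    S <- state[[1]]; M <- state[[2]]; T <- state[[3]]
  }
  p <- feedback_probability(M, hp)
  nu <- feedback_division_rate(M, hp)
  sat <- T / (cp$m2 + T)
  supp <- 1 - tx$A1 * cp$eps * sat
  c(dS = (2 * p - 1) * nu * supp * S - tx$A2 * cp$dS * sat * S,
    dM = 2 * (1 - p) * nu * supp * S - (tx$A4 * hp$d0 + tx$A3 * cp$dM * sat) * M,
    dT = tumor_rate(T, tp))
}

#' Closed-form healthy steady state
#'
#' At homeostasis the self-renewal probability must equal 1/2, which pins
#' the muscle volume at `Mss = m (2(p0+p1) - 1) / (1 - 2 p0)`; the satellite
#' volume follows from the muscle balance:
#' `Sss = 2 m d0 p1 (2(p0+p1) - 1) / ((1 - 2 p0) (2 p1 nu0 + (1 - 2 p0) nu1))`.
#' Requires `p0 < 1/2 < p0 + p1`; violated inequalities are reported by
#' name rather than returning a negative volume.
#'
#' @param hp a [healthy_params()] object.
#' @return Named numeric `c(S = Sss, M = Mss)` in mm^3.
#' @export
steady_state <- function(hp) {
  assert_homeostatic(hp)
  Mss <- hp$m * (2 * (hp$p0 + hp$p1) - 1) / (1 - 2 * hp$p0)
  Sss <- 2 * hp$m * hp$d0 * hp$p1 * (2 * (hp$p0 + hp$p1) - 1) /
    ((1 - 2 * hp$p0) * (2 * hp$p1 * hp$nu0 + (1 - 2 * hp$p0) * hp$nu1))
  c(S = Sss, M = Mss)
}

#' Steady-state stem cell ratio
#'
#' The homeostatic satellite-to-muscle ratio
#' `psi_ss = 2 d0 p1 / (2 p1 nu0 + (1 - 2 p0) nu1)`, algebraically equal to
#' `Sss/Mss` and bounded above by `d0/nu0` (death rate over homeostatic
#' division rate).
#'
#' @param hp a [healthy_params()] object with `p0 < 1/2 < p0 + p1`.
#' @return Dimensionless ratio.
#' @export
steady_state_stem_ratio <- function(hp) {
  assert_homeostatic(hp)
  2 * hp$d0 * hp$p1 / (2 * hp$p1 * hp$nu0 + (1 - 2 * hp$p0) * hp$nu1)
}

#' Large-tumor effective muscle death rate under treatment
#'
#' In the limit of a large tumor the muscle loss coefficient of the treated
#' system is `A4 d0 + A3 dM`; it governs the treated lean-mass equilibrium
#' and explains why late treatment leaves a higher residual death rate.
#'
#' @param hp,cp healthy and cachexia parameter objects.
#' @param tx a [treatment_params()] object.
#' @return Rate in per day.
#' @export
effective_muscle_death <- function(hp, cp, tx) {
  stopifnot(inherits(hp, "healthy_params"), inherits(cp, "cachexia_params"),
            inherits(tx, "treatment_params"))
  tx$A4 * hp$d0 + tx$A3 * cp$dM
}

#' Initial compartment volumes from a day-0 body weight
#'
#' Splits the lean fraction of a cohort's average implantation-day weight
#' into the two compartments while preserving a reference stem ratio
#' (typically the day-49 ratio of the healthy solve, so the feedback state
#' is age-appropriate): `M0 = lean_fraction W / ((1 + psi_ref) xi)` and
#' `S0 = psi_ref M0`.
#'
#' @param W body weight (g), `>= 0`.
#' @param psi_ref reference stem ratio `S/M`, `> 0`.
#' @param conv a [conversion_convention()].
#' @return Named numeric `c(S = S0, M = M0)` in mm^3.
#' @export
initial_conditions_from_weight <- function(W, psi_ref,
                                           conv = conversion_convention()) {
  stopifnot(inherits(conv, "conversion_convention"))
  if (W < 0) stop("body weight W must be non-negative", call. = FALSE)
  if (psi_ref <= 0) stop("psi_ref must be positive", call. = FALSE)
  M0 <- conv$lean_fraction * W / ((1 + psi_ref) * conv$xi)
  c(S = psi_ref * M0, M = M0)
}

#' Deconstruct body weight into lean compartments
#'
#' Applies the fixed shares of the conversion convention: after subtracting
#' any tumor mass, the lean fraction of the remaining weight is split into
#' muscle and satellite mass and converted to volume by `xi`.
#'
#' @param W body weight (g); vectorised.
#' @param conv a [conversion_convention()].
#' @param tumor_mass predicted tumor mass (g) to subtract before the lean
#'   deconstruction; must not exceed `W`.
#' @return A data frame with columns `stem_mass_g`, `muscle_mass_g`,
#'   `stem_mm3`, `muscle_mm3`.
#' @export
weight_to_lean_compartments <- function(W, conv = conversion_convention(),
                                        tumor_mass = 0) {
  stopifnot(inherits(conv, "conversion_convention"))
  if (any(tumor_mass < 0)) stop("tumor_mass must be non-negative", call. = FALSE)
  if (any(tumor_mass > W)) {
    stop("tumor_mass exceeds body weight W", call. = FALSE)
  }
  lean <- conv$lean_fraction * (W - tumor_mass)
  data.frame(stem_mass_g = conv$stem_share * lean,
             muscle_mass_g = conv$muscle_share * lean,
             stem_mm3 = conv$stem_share * lean / conv$xi,
             muscle_mm3 = conv$muscle_share * lean / conv$xi)
}
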