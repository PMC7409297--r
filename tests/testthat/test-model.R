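# Closed-form algebra and right-hand sides of the model family.

test_that("feedback laws hit their limits and half-saturation values", {
  expect_equal(feedback_probability(0, hp_fit), 0.612)
  expect_equal(feedback_probability(1e12, hp_fit), 0.479, tolerance = 1e-9)
  expect_equal(feedback_division_rate(0, hp_fit), 5.678)
  expect_equal(feedback_division_rate(1000, hp_fit), 0.087 + 5.591 / 2)
  # at the closed-form equilibrium the self-renewal probability is exactly 1/2
  Mss <- steady_state(hp_fit)[["M"]]
  expect_equal(feedback_probability(Mss, hp_fit), 0.5, tolerance = 1e-12)
  # hand arithmetic: 0.087 + 5.591 * 3/19
  expect_equal(feedback_division_rate(Mss, hp_fit), 0.087 + 5.591 * 3 / 19,
               tolerance = 1e-12)
  expect_error(feedback_probability(-1, hp_fit), "non-negative")
  expect_error(feedback_division_rate(-1, hp_fit), "non-negative")
})

test_that("healthy rates vanish at the steady state and follow hand arithmetic", {
  ss <- steady_state(hp_fit)
  expect_equal(unname(healthy_rates(ss, hp_fit)), c(0, 0),
               tolerance = 1e-9 * ss[["M"]])
  # empty stem pool: only natural muscle death remains
  r <- healthy_rates(tissue_state(S = 0, M = 123), hp_fit)
  expect_identical(r[["dS"]], 0)
  expect_equal(r[["dM"]], -0.05 * 123)
  # hand evaluation at M = 0: (2*0.612 - 1) * 5.678 * 100
  r2 <- healthy_rates(c(100, 0), hp_fit)
  expect_equal(r2[["dS"]], 127.1872, tolerance = 1e-10)
  expect_error(healthy_rates(tissue_state(1, 1, T = 1), hp_fit), "tumor-free")
})

test_that("closed-form steady state matches hand arithmetic and scales with m", {
  ss <- steady_state(hp_fit)
  expect_equal(ss[["M"]], 1000 * 0.224 / 0.042, tolerance = 1e-12)
  expect_equal(ss[["S"]], 274.9738, tolerance = 1e-6)
  hp2 <- healthy_params(0.479, 0.133, 0.087, 5.591, 0.05, 2000)
  expect_equal(unname(steady_state(hp2)), unname(2 * ss), tolerance = 1e-12)
})

test_that("steady-state preconditions are reported by named inequality", {
  expect_error(steady_state(healthy_params(0.55, 0.2, 0.1, 1, 0.05, 1000)),
               "p0 < 1/2")
  expect_error(steady_state(healthy_params(0.2, 0.2, 0.1, 1, 0.05, 1000)),
               "1/2 < p0 \\+ p1")
})

test_that("steady-state stem ratio equals Sss/Mss and obeys the d0/nu0 bound", {
  expect_equal(steady_state_stem_ratio(hp_fit), 0.0516, tolerance = 1e-3)
  set.seed(11)
  for (i in 1:100) {
    hp <- random_homeostatic_params()
    ss <- steady_state(hp)
    psi <- steady_state_stem_ratio(hp)
    expect_equal(psi, ss[["S"]] / ss[["M"]], tolerance = 1e-12)
    expect_lte(psi, hp$d0 / hp$nu0)
    r <- healthy_rates(ss, hp)
    expect_lt(max(abs(r)), 1e-9 * ss[["M"]])
  }
  # p0 -> 1/2 from below drives the ratio to its upper bound
  hp_lim <- healthy_params(0.4999999, 0.133, 0.087, 5.591, 0.05, 1000)
  expect_equal(steady_state_stem_ratio(hp_lim), 0.05 / 0.087,
               tolerance = 1e-4)
})

test_that("tumor rate interpolates exponential and linear phases", {
  expect_identical(tumor_rate(0, tp_fit), 0)
  expect_equal(tumor_rate(1e9, tp_fit), 116.0, tolerance = 1e-8)
  Tth <- transition_threshold(tp_fit)
  expect_equal(tumor_rate(Tth, tp_fit), 116.0 * 2^(-1 / 20),
               tolerance = 1e-12)
  # strictly increasing through the transition, saturating at mu1 beyond it
  Ts <- c(0.5, 5, 50, 260, 500)
  rates <- tumor_rate(Ts, tp_fit)
  expect_true(all(diff(rates) > 0))
  far <- tumor_rate(c(500, 2000, 5000, 1e8, 1e12), tp_fit)
  expect_true(all(diff(far) >= 0))
  expect_true(all(far <= 116.0 + 1e-9))
  expect_error(tumor_rate(-1, tp_fit), "non-negative")
})

test_that("transition threshold is mu1/mu and scales linearly", {
  expect_equal(signif(transition_threshold(tp_fit), 3), 260)
  expect_equal(transition_threshold(tumor_params(1, 1)), 1)
  expect_equal(transition_threshold(tumor_params(0.446, 232)),
               2 * transition_threshold(tp_fit))
})

test_that("suppression factor saturates between 1 - eps and 1", {
  cp <- cachexia_params(eps = 0.4, dS = 0, dM = 0, m2 = 100)
  expect_identical(suppression_factor(0, cp), 1)
  expect_equal(suppression_factor(100, cp), 1 - 0.2)
  expect_equal(suppression_factor(1e12, cp), 0.6, tolerance = 1e-9)
})

test_that("cachexia rates reduce to the healthy system and match a term-by-term oracle", {
  st <- group_a_state()
  # no tumor: all cachectic factors vanish
  r0 <- cachexia_rates(tissue_state(st$S, st$M, T = 0), hp_fit, cp_fit, tp_fit)
  rh <- healthy_rates(c(st$S, st$M), hp_fit)
  expect_identical(r0[["dS"]], rh[["dS"]])
  expect_identical(r0[["dM"]], rh[["dM"]])
  expect_identical(r0[["dT"]], 0)
  # zero perturbation: healthy rates regardless of tumor size
  cp0 <- cachexia_params(0, 0, 0, 338)
  r1 <- cachexia_rates(tissue_state(st$S, st$M, T = 700), hp_fit, cp0, tp_fit)
  expect_identical(r1[["dS"]], rh[["dS"]])
  expect_identical(r1[["dM"]], rh[["dM"]])
  # independent term-by-term evaluation at the implantation-day state
  S <- 252.75; M <- 4799.25; T <- 0.5
  p <- 0.479 + 0.133 / (1 + M / 1000)
  nu <- 0.087 + 5.591 / (1 + M / 1000)
  sat <- T / (338 + T)
  supp <- 1 - 0.004 * sat
  oracle <- c((2 * p - 1) * nu * supp * S - 0.030 * sat * S,
              2 * (1 - p) * nu * supp * S - (0.05 + 0.104 * sat) * M,
              0.446 * T * (1 + (0.446 * T / 116)^20)^(-1 / 20))
  got <- cachexia_rates(tissue_state(S, M, T = T), hp_fit, cp_fit, tp_fit)
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("treatment rates form a reduction chain down to the healthy system", {
  st <- tissue_state(200, 4000, T = 900)
  tx1 <- treatment_params(1, 1, 1, 1, t_start = 0)
  expect_identical(treatment_rates(st, hp_fit, cp_fit, tp_fit, tx1),
                   cachexia_rates(st, hp_fit, cp_fit, tp_fit))
  # full blockade at enormous tumor: muscle loss reverts to natural d0
  tx0 <- treatment_params(0, 0, 0, 1, t_start = 0)
  big <- tissue_state(200, 4000, T = 1e10)
  r <- treatment_rates(big, hp_fit, cp_fit, tp_fit, tx0)
  rh <- healthy_rates(c(200, 4000), hp_fit)
  expect_equal(r[["dS"]], rh[["dS"]], tolerance = 1e-9)
  expect_equal(r[["dM"]], rh[["dM"]], tolerance = 1e-9)
  expect_error(treatment_params(1.2, 0, 0, 1), "A1")
})

test_that("effective treated muscle death rate matches the fitted groups", {
  expect_equal(round(effective_muscle_death(hp_fit, cp_fit, tx_a), 2), 0.08)
  expect_equal(round(effective_muscle_death(hp_fit, cp_fit, tx_b), 2), 0.11)
  tx_none <- treatment_params(1, 1, 1, 1)
  expect_equal(effective_muscle_death(hp_fit, cp_fit, tx_none), 0.154)
})

test_that("initial conditions from weight preserve the reference stem ratio", {
  psi <- 0.05266544
  ic <- initial_conditions_from_weight(25.26, psi)
  expect_equal(ic[["M"]], 4799.25, tolerance = 1e-5)
  expect_equal(ic[["S"]], 252.75, tolerance = 1e-4)
  icB <- initial_conditions_from_weight(25.10, psi)
  expect_equal(icB[["M"]], 4768.85, tolerance = 1e-5)
  expect_equal(unname(initial_conditions_from_weight(0, psi)), c(0, 0))
  expect_equal(ic[["S"]] / ic[["M"]], psi, tolerance = 1e-12)
})

test_that("lean deconstruction applies the 40/95/5 shares", {
  lc <- weight_to_lean_compartments(11.26)
  expect_equal(lc$muscle_mass_g, 4.2788)
  expect_equal(lc$stem_mass_g, 0.2252)
  expect_equal(lc$muscle_mm3, 2139.4)
  expect_equal(lc$stem_mm3, 112.6)
  expect_equal(lc$stem_mass_g / lc$muscle_mass_g, 1 / 19, tolerance = 1e-12)
  # tumor-only carcass: everything subtracted
  z <- weight_to_lean_compartments(2, tumor_mass = 2)
  expect_true(all(unlist(z) == 0))
  expect_error(weight_to_lean_compartments(2, tumor_mass = 3), "exceeds")
})

test_that("parameter validation is eager and serialization round-trips", {
  expect_error(healthy_params(0.6, 0.6, 0.1, 1, 0.05, 1000), "p0 \\+ p1")
  expect_error(cachexia_params(1.5, 0, 0, 100), "eps")
  expect_error(tumor_params(0, 1), "mu")
  expect_error(logistic_params(0.1, 20, 25), "W0")
  expect_error(conversion_convention(muscle_share = 0.9, stem_share = 0.2),
               "must equal 1")
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(hp_fit, path)
    expect_equal(read_params(path, "healthy"), hp_fit)
  }
  expect_error(read_params("no/such/file.json", "healthy"), "does not exist")
})
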