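# Rate parameterization: derived death rate, age power laws, covariate and
# dose modification, and the closed-form planning helpers.

test_that("beta is derived from the effective proliferation rate", {
  expect_equal(beta_from_rates(rate_set(nu0N = 1, gamma = 0, nu1 = 12,
                                        alpha = 12)), 0)
  expect_equal(beta_from_rates(reference_fit_rates()), 12 - 0.12 - 1.3)
  # infeasible corner of the allowed fitting box
  expect_error(rate_set(nu0N = 1, gamma = 0.3, nu1 = 12, alpha = 12),
               "infeasible")
})

test_that("age power law matches its closed form and reference points", {
  law <- age_power_law("nu0N", psi = 1)
  expect_equal(law$a0, 10)
  # reported age-dependent uptake fit: 2.4/y at age 10 rising linearly
  expect_equal(age_scaled(2.4, law, age = 50), 2.4 * 60 / 20)
  # reported age-dependent gamma fit at old age
  lawg <- age_power_law("gamma", psi = -0.85)
  expect_equal(lawg$a0, 40)
  expect_equal(age_scaled(0.10, lawg, age = 90), 0.10 * (100 / 50)^-0.85,
               tolerance = 1e-12)
  expect_equal(age_scaled(0.10, lawg, age = 90), 0.0555, tolerance = 1e-2)
  # trivial contracts
  expect_equal(age_scaled(3, age_power_law("nu1", psi = 0), age = 77), 3)
  expect_equal(age_scaled(3, age_power_law("nu2", psi = 0.6), age = 60), 3)
  expect_error(age_power_law("nu0N", psi = 1.5), "psi")
})

test_that("age scaling is monotone with the sign of the exponent", {
  ages <- seq(0, 100, by = 5)
  for (psi in c(-1, -0.3, 0.4, 1)) {
    v <- age_scaled(1, age_power_law("gamma", psi = psi), ages)
    if (psi > 0) expect_true(all(diff(v) > 0))
    else expect_true(all(diff(v) < 0))
  }
})

test_that("dose modification is linear with guarded positivity", {
  ctx <- parameter_context(age = 50, cumulative_dose = 2,
                           annual_dose_rate = 0.1)
  expect_equal(dose_modified(1, dose_response("nu2", "cumulative_dose", 0),
                             ctx), 1)
  # reported empirical ERR slope applied as a rate factor
  expect_equal(dose_modified(1, dose_response("nu2", "cumulative_dose",
                                              0.13), ctx), 1.26)
  expect_equal(dose_modified(2, dose_response("nu1", "annual_dose_rate",
                                              0.5), ctx), 2 * 1.05)
  expect_error(dose_modified(1, dose_response("nu2", "cumulative_dose",
                                              -1), ctx),
               "invalid")
})

test_that("rate composition applies law, modifier and dose in order", {
  base <- prevalence_study_rates()
  # identity composition
  same <- evaluate_rates(base)
  expect_equal(unclass(same), unclass(base))
  idmod <- covariate_modifier("nu2", "blood_pressure",
                              c(normal = 1, hypertensive = 1, unknown = 1))
  ctx <- parameter_context(age = 40,
                           covariates = list(blood_pressure = "normal"))
  expect_equal(unclass(evaluate_rates(base, modifiers = list(idmod),
                                      context = ctx)),
               unclass(base))
  # single modifier scales only its target
  mod2 <- covariate_modifier("nu2", "blood_pressure",
                             c(normal = 1, hypertensive = 2, unknown = 1))
  ctx2 <- parameter_context(age = 40,
                            covariates = list(blood_pressure =
                                                "hypertensive"))
  r2 <- evaluate_rates(base, modifiers = list(mod2), context = ctx2)
  expect_equal(r2$nu2, 2 * base$nu2)
  expect_equal(r2$nu1, base$nu1)
  # composed law + dose factor agrees with the manual product
  law <- age_power_law("nu0N", psi = 1, a0 = 10)
  dr <- dose_response("nu1", "annual_dose_rate", lambda = 0.5)
  ctx3 <- parameter_context(age = 50, annual_dose_rate = 0.1)
  r3 <- evaluate_rates(base, laws = list(law), dr = dr, context = ctx3)
  expect_equal(r3$nu0N, base$nu0N * 3)
  expect_equal(r3$nu1, base$nu1 * 1.05)
  # duplicate laws rejected
  expect_error(evaluate_rates(base, laws = list(law, law)), "one age")
})

test_that("feasibility of the composed rates is checked after the laws", {
  base <- rate_set(nu0N = 3, gamma = 0.2, nu1 = 1, alpha = 1.3)
  law <- age_power_law("alpha", psi = -1)
  # alpha shrinks with age until beta = alpha - gamma - nu1 < 0
  expect_error(evaluate_rates(base, laws = list(law),
                              context = parameter_context(age = 100)),
               "infeasible")
})

test_that("proliferation bound reproduces the growth-argument estimate", {
  # 10^2 -> 10^7 cells in 50 years with nu1/gamma = 3
  b <- proliferation_bound(1e7, 1e2, 3, 50)
  expect_equal(round(b, 1), 0.2)
  expect_equal(b, (log(1e5) - log(3)) / 50, tolerance = 1e-12)
  expect_equal(proliferation_bound(1e7, 1e2, 1, 50), log(1e5) / 50,
               tolerance = 1e-12)
  expect_equal(proliferation_bound(300, 100, 3, 10), 0)
  expect_error(proliferation_bound(1e2, 1e7, 3, 50), "exceed")
})

test_that("attributable fraction is ERR*d/(1+ERR*d), increasing, in [0,1)", {
  expect_equal(attributable_fraction(0, 5), 0)
  expect_equal(attributable_fraction(0.1, 2), 0.2 / 1.2)
  expect_lt(attributable_fraction(0.1, 2), 0.20)
  expect_equal(attributable_fraction(0.1, 0.43), 0.043 / 1.043,
               tolerance = 1e-12)
  af <- vapply(seq(0, 10, by = 0.5),
               function(d) attributable_fraction(0.1, d), 0)
  expect_true(all(diff(af) > 0))
  expect_true(all(af >= 0 & af < 1))
})

test_that("feasible box rate sets always have nonnegative beta", {
  set.seed(7)
  for (i in 1:50) {
    g <- runif(1, 0.1, 0.3); n1 <- runif(1, 0.1, 12)
    if (g + n1 <= 12) {
      r <- rate_set(nu0N = runif(1, 1, 10), gamma = g, nu1 = n1)
      expect_gte(beta_from_rates(r), 0)
    } else {
      expect_error(rate_set(nu0N = 2, gamma = g, nu1 = n1))
    }
  }
})
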