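# Analytic survival solver: closed forms, probability bounds, internal
# consistency and agreement with the stochastic simulator.

test_that("foam-cell safe probability is the exponential nu2 integral", {
  tl <- constant_timeline(prevalence_study_rates(), max_age = 100)
  expect_equal(foam_cell_safe_prob(tl, 10, 10), 1)
  expect_equal(foam_cell_safe_prob(tl, 30, 40), exp(-1e-6),
               tolerance = 1e-12)
  tl0 <- constant_timeline(prevalence_study_rates(nu2 = 0))
  expect_equal(foam_cell_safe_prob(tl0, 0, 90), 1)
  # multiplicative over adjacent intervals
  expect_equal(foam_cell_safe_prob(tl, 10, 50),
               foam_cell_safe_prob(tl, 10, 30) *
                 foam_cell_safe_prob(tl, 30, 50), tolerance = 1e-12)
  expect_error(foam_cell_safe_prob(tl, 50, 30), "s <= t")
})

test_that("macrophage lineage probability solves the backward equation", {
  # nu2 = 0: u identically 1 (fixed point)
  tl0 <- constant_timeline(prevalence_study_rates(nu2 = 0))
  expect_equal(macrophage_safe_prob(tl0, c(0, 20, 50), 60), rep(1, 3),
               tolerance = 1e-9)
  # alpha = beta = 0: two-stage exponential race, analytic oracle
  nu1 <- 0.8; nu2 <- 1e-3
  tl <- constant_timeline(rate_set(nu0N = 2, gamma = -nu1, nu1 = nu1,
                                   alpha = 0, nu2 = nu2), max_age = 100)
  tau <- seq(0, 50, by = 2.5)
  u <- macrophage_safe_prob(tl, 50 - tau, 50)
  u_cf <- exp(-nu1 * tau) +
    nu1 * (exp(-nu2 * tau) - exp(-nu1 * tau)) / (nu1 - nu2)
  expect_lt(max(abs(u - u_cf)), 1e-6)
  expect_true(all(u > 0 & u <= 1))
})

test_that("lineage extinction probability matches a single-seed simulation", {
  # one macrophage seeded, no immigration: P(no plaque by tau) = u
  r <- rate_set(nu0N = 0, gamma = 0.1, nu1 = 1, alpha = 2, nu2 = 1e-3)
  tl <- constant_timeline(r, max_age = 60)
  tau <- 20
  n <- 600
  set.seed(17)
  safe <- replicate(n, {
    st <- list(age = 0, M = 1, F = 0, R = 0)
    for (i in seq_len(tau * 40)) {
      st <- lesion_step(st, r, dt = 1 / 40)
      if (st$R > 0) break
      if (st$M == 0 && st$F == 0) break  # extinct: safe forever
    }
    st$R == 0
  })
  u <- macrophage_safe_prob(tl, 0, tau)
  se <- sqrt(u * (1 - u) / n)
  expect_lt(abs(mean(safe) - u), 3 * se + 0.01)
})

test_that("plaque-free survival has its trivial limits", {
  expect_equal(survival_no_plaque(
    constant_timeline(rate_set(nu0N = 0, gamma = 0.2, nu1 = 1)),
    c(10, 50, 90)), rep(1, 3), tolerance = 1e-9)
  expect_equal(survival_no_plaque(
    constant_timeline(prevalence_study_rates(nu2 = 0)), c(10, 50, 90)),
    rep(1, 3), tolerance = 1e-9)
  S <- survival_no_plaque(constant_timeline(prevalence_study_rates(nu2 = 1e-5)),
                          seq(0, 100, by = 5))
  expect_true(all(diff(S) <= 0))
  expect_true(all(S > 0 & S <= 1))
})

test_that("time-homogeneous survival matches quadrature of the closed form", {
  # alpha = beta = 0: u has a closed form, so S_R follows by quadrature
  nu0N <- 2; nu1 <- 0.8; nu2 <- 1e-3
  tl <- constant_timeline(rate_set(nu0N = nu0N, gamma = -nu1, nu1 = nu1,
                                   alpha = 0, nu2 = nu2), max_age = 80)
  u_cf <- function(tau) exp(-nu1 * tau) +
    nu1 * (exp(-nu2 * tau) - exp(-nu1 * tau)) / (nu1 - nu2)
  for (t0 in c(10, 30, 60)) {
    I <- stats::integrate(function(x) 1 - u_cf(x), 0, t0,
                          rel.tol = 1e-10)$value
    expect_equal(survival_no_plaque(tl, t0), exp(-nu0N * I),
                 tolerance = 1e-6)
  }
})

test_that("stroke grid applies the lag and matches exp(-integral h)", {
  tl <- constant_timeline(prevalence_study_rates(nu2 = 1e-5), max_age = 100)
  ages <- seq(0, 100, by = 0.25)
  g <- stroke_hazard_survival(tl, ages)
  expect_true(all(g$S[g$age <= 10] == 1))
  expect_true(all(g$h[g$age <= 10] == 0))
  # internal identity to relative error < 1e-4
  H <- atheromod:::cumtrapz(g$age, g$h)
  expect_lt(max(abs(exp(-H) / g$S - 1)), 1e-4)
  # hazard rises steeply with age for constant rates
  h_mid <- g$h[g$age %in% 40:80]
  expect_true(all(diff(h_mid) > 0))
})

test_that("inhomogeneous path agrees with the homogeneous fast path", {
  r <- prevalence_study_rates(nu2 = 1e-5)
  tl1 <- constant_timeline(r, max_age = 90)
  # same rates split over two intervals forces the backward-sweep path
  tl2 <- parameter_timeline(list(r, r), breakpoints = c(0, 35),
                            max_age = 90)
  ages <- c(20, 40, 60, 80)
  g1 <- stroke_hazard_survival(tl1, ages)
  g2 <- stroke_hazard_survival(tl2, ages, hazard_method = "fd")
  g3 <- stroke_hazard_survival(tl2, ages, hazard_method = "augmented")
  # backward sweep uses coarser quadrature nodes than the fast path
  expect_equal(g2$S, g1$S, tolerance = 1e-4)
  expect_equal(g3$S, g1$S, tolerance = 1e-4)
  expect_equal(g2$h, g1$h, tolerance = 1e-3)
  expect_equal(g3$h, g1$h, tolerance = 1e-4)
})

test_that("a genuinely age-dependent timeline changes the hazard", {
  base <- prevalence_study_rates(nu2 = 1e-5)
  law <- age_power_law("nu0N", psi = 1)
  tl_law <- timeline_from_evaluator(function(a)
    evaluate_rates(base, laws = list(law),
                   context = parameter_context(age = a)), max_age = 90)
  g_law <- stroke_hazard_survival(tl_law, c(30, 60, 80))
  g_const <- stroke_hazard_survival(constant_timeline(base, 90),
                                    c(30, 60, 80))
  # rising uptake shifts risk to older ages
  expect_lt(g_law$h[1] / g_const$h[1], g_law$h[3] / g_const$h[3])
})

test_that("analytic survival agrees with the simulator across the box", {
  sets <- list(prevalence_study_rates(nu2 = 1e-5),
               rate_set(nu0N = 8, gamma = 0.28, nu1 = 3, nu2 = 1e-5))
  n <- 400
  for (r in sets) {
    tl <- constant_timeline(r, max_age = 75)
    sim <- atheromod:::simulate_batch(function(a) r, n, 70,
                                      steps_per_year = 100, seed = 99,
                                      track_counts = FALSE)
    for (a in c(50, 70)) {
      S_mc <- mean(is.na(sim$first_plaque) | sim$first_plaque > a)
      S_an <- survival_no_plaque(tl, a)
      se <- sqrt(S_an * (1 - S_an) / n)
      expect_lt(abs(S_mc - S_an), 3 * se + 0.01)
    }
  }
})

test_that("relative risk declines with age for a late-stage multiplier", {
  r <- reference_fit_rates()
  r2 <- rate_set(nu0N = r$nu0N, gamma = r$gamma, nu1 = r$nu1,
                 alpha = r$alpha, nu2 = 2 * r$nu2, t_lag = r$t_lag)
  ages <- c(12, seq(20, 90, by = 10))
  rr <- relative_risk(constant_timeline(r2, 100),
                      constant_timeline(r, 100), ages)
  expect_equal(rr$rr[1], 2, tolerance = 0.02)
  # just above the lag both hazards are tiny and the ratio sits at the
  # multiplier; the selection-driven decline is strict once risk is real
  expect_true(all(diff(rr$rr[rr$age >= 20]) < 0))
  expect_true(all(rr$rr <= 2 + 1e-3 & rr$rr >= 1))
  same <- relative_risk(constant_timeline(r, 100),
                        constant_timeline(r, 100), ages)
  expect_equal(same$rr, rep(1, length(ages)), tolerance = 1e-9)
})
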