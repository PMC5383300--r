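# Empirical baseline model: hazard evaluation, exact survival integrals
# and the age profile of the excess relative risk.

test_that("hazard composes baseline, factors and the dose term", {
  m <- empirical_model(intercept = -6, age_slopes = c(0.08, 0, 0),
                       err_lambda = 0.13, err_mu = 64)
  base50 <- exp(-6 + 0.08 * (50 - 60))
  expect_equal(empirical_hazard(m, 50), base50 * 1)  # zero dose
  expect_equal(empirical_hazard(m, 50, cumulative_dose = 1),
               base50 * 1.13, tolerance = 1e-12)
  # at and above the cutoff the dose has no effect
  base70 <- exp(-6 + 0.08 * 10)
  expect_equal(empirical_hazard(m, 70, cumulative_dose = 5), base70)
  # covariate factor multiplies exactly
  mf <- empirical_model(intercept = -6, age_slopes = c(0.08, 0, 0),
                        covariate_factors = list(blood_pressure = c(
                          normal = 1, hypertensive = 1.8, unknown = 1)))
  expect_equal(
    empirical_hazard(mf, 50,
                     covariates = list(blood_pressure = "hypertensive")) /
      empirical_hazard(mf, 50,
                       covariates = list(blood_pressure = "normal")),
    1.8, tolerance = 1e-12)
  mneg <- empirical_model(err_lambda = -0.3, err_mu = Inf)
  expect_error(empirical_hazard(mneg, 50, cumulative_dose = 5), "ERR")
})

test_that("empirical survival matches closed-form exponentials", {
  # constant hazard: flat log-hazard in age and calendar
  h0 <- 0.01
  m <- empirical_model(intercept = log(h0), age_slopes = c(0, 0, 0))
  rec <- list(birth_year = 1930, smoking = "nonsmoker",
              blood_pressure = "normal", graduation = "none")
  g <- empirical_survival(m, rec, grid = seq(40, 60, by = 1))
  expect_equal(g$S, exp(-h0 * (g$age - 40)), tolerance = 1e-10)
  expect_equal(g$h, rep(h0, nrow(g)), tolerance = 1e-12)
  # zero hazard
  m0 <- empirical_model(intercept = -60, age_slopes = c(0, 0, 0))
  g0 <- empirical_survival(m0, rec, grid = seq(40, 60, by = 5))
  expect_equal(g0$S, rep(1, nrow(g0)), tolerance = 1e-10)
  # two-segment piecewise-constant hazard via an age-knot slope change is
  # the product of segment exponentials
  # log h = log(h0) for a < 60 and log(h1) above via a steep knot: instead
  # use two explicit models and splice the exact integrals
  h1 <- 0.03
  m2 <- empirical_model(intercept = log(h1), age_slopes = c(0, 0, 0))
  S_spliced <- exp(-h0 * 10) * exp(-h1 * 5)
  g1 <- empirical_survival(m, rec, grid = c(50, 60))
  g2 <- empirical_survival(m2, rec, grid = c(60, 65))
  expect_equal(g1$S[2] * g2$S[2], S_spliced, tolerance = 1e-10)
})

test_that("empirical survival integrates the spline exactly", {
  # non-trivial slopes and calendar effect: compare against brute-force
  # quadrature of the hazard
  m <- empirical_model(intercept = -5.5, age_slopes = c(0.07, 0.02, -0.01),
                       cal_slopes = c(0.01, -0.005, 0))
  rec <- list(birth_year = 1925, smoking = "nonsmoker",
              blood_pressure = "normal", graduation = "none")
  g <- empirical_survival(m, rec, grid = c(35, 45, 62, 70.5))
  H_quad <- function(a1, a2) {
    f <- function(a) empirical_hazard(m, a, 1925 + floor(a + 1e-9))
    sum(vapply(seq(a1, a2 - 0.25, by = 0.25), function(x)
      stats::integrate(f, x, x + 0.25, rel.tol = 1e-12,
                       stop.on.error = FALSE)$value, 0))
  }
  expect_equal(-log(g$S[4]), H_quad(35, 70.5), tolerance = 1e-6)
})

test_that("ERR age profile is flat below the cutoff and 1 above", {
  m <- empirical_model(err_lambda = 0.13, err_mu = 64)
  p <- err_age_profile(m, ages = c(30, 50, 63.9, 64, 80), dose = 2)
  expect_equal(p$rr, c(1.26, 1.26, 1.26, 1, 1), tolerance = 1e-12)
  expect_equal(err_age_profile(m, c(30, 80), dose = 0)$rr, c(1, 1))
  # age-independent variant: cutoff at infinity
  mInf <- empirical_model(err_lambda = 0.13, err_mu = Inf)
  pI <- err_age_profile(mInf, ages = seq(20, 100, by = 20), dose = 2)
  expect_true(all(pI$rr == 1.26))
})

test_that("a multiplicative covariate gives an exactly constant ratio", {
  k <- 1.7
  m <- empirical_model(intercept = -6, age_slopes = c(0.08, 0.01, 0),
                       covariate_factors = list(blood_pressure = c(
                         normal = 1, hypertensive = k, unknown = 1)))
  ages <- seq(20, 95, by = 2.5)
  ratio <- empirical_hazard(m, ages,
                            covariates = list(blood_pressure =
                                                "hypertensive")) /
    empirical_hazard(m, ages, covariates = list(blood_pressure = "normal"))
  expect_equal(ratio, rep(k, length(ages)), tolerance = 1e-12)
})

test_that("empirical deviance agrees with the per-worker formula", {
  g <- small_synth()
  co <- g$cohort
  co$workers <- co$workers[1:40, ]
  co$doses <- co$doses[co$doses$id %in% co$workers$id, ]
  m <- empirical_model(intercept = -5.8, age_slopes = c(0.08, 0, 0),
                       cal_slopes = c(0.002, 0, 0), err_lambda = 0.13,
                       err_mu = 64)
  dev <- cohort_deviance(co, m)
  histories <- atheromod:::dose_histories(co)
  ll <- 0
  for (i in seq_len(nrow(co$workers))) {
    w <- co$workers[i, ]
    h <- histories[[w$id]]
    covs <- as.list(w[c("smoking", "blood_pressure", "graduation")])
    H <- atheromod:::emp_cumhaz(m, w$birth_year, covs, h, w$age_in,
                                w$age_out)
    ll <- ll - H
    if (w$event == 1)
      ll <- ll + log(empirical_hazard(
        m, w$age_out, w$birth_year + floor(w$age_out - 1e-9), covs,
        atheromod:::cumulative_dose_at(h, w$age_out)))
  }
  expect_equal(dev, -2 * ll, tolerance = 1e-8)
})
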