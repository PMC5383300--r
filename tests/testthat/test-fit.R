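# Maximum-likelihood fitting: pure evaluation, parameter recovery,
# profile intervals against a brute-force scan, nested-model tests and the
# risk-factor target scan.

test_that("a fit with no free parameters is a pure evaluation", {
  g <- small_synth()
  co <- g$cohort
  truth <- reference_fit_rates()
  fit <- fit_stroke_model(co, free = character(0),
                          fixed = list(nu0N = 4.5, gamma = 0.12,
                                       nu1 = 1.3),
                          reference_deviance = 100, n_starts = 1)
  expect_equal(fit$minus2logl,
               cohort_deviance(co, mechanistic_model(truth)),
               tolerance = 1e-10)
  expect_equal(fit$delta_dev, fit$minus2logl - 100)
  expect_length(coef(fit), 0)
  expect_true(fit$converged)
})

test_that("one-parameter fit recovers truth; profile matches a scan", {
  g <- small_synth()
  co <- g$cohort
  fit <- fit_stroke_model(co, free = "nu0N",
                          fixed = list(gamma = 0.12, nu1 = 1.3),
                          n_starts = 2, seed = 3)
  expect_true(fit$converged)
  ci <- profile_ci(fit, "nu0N")
  expect_gt(ci$upper, ci$lower)
  expect_true(ci$lower <= 4.5 && 4.5 <= ci$upper)
  # brute-force deviance scan as the oracle for the interval bounds
  devs <- vapply(seq(1, 10, by = 0.05), function(v)
    cohort_deviance(co, mechanistic_model(
      rate_set(nu0N = v, gamma = 0.12, nu1 = 1.3))), 0)
  xs <- seq(1, 10, by = 0.05)
  target <- min(devs) + qchisq(0.95, 1)
  inside <- xs[devs <= target]
  expect_equal(ci$lower, min(inside), tolerance = 0.05)
  expect_equal(ci$upper, max(inside), tolerance = 0.05)
  expect_equal(fit$minus2logl, min(devs), tolerance = 0.05)
  # logLik method agrees with the deviance
  expect_equal(-2 * as.numeric(logLik(fit)), fit$minus2logl)
  expect_equal(attr(logLik(fit), "df"), 1)
})

test_that("fits are reproducible from (data, seed)", {
  g <- small_synth()
  f1 <- fit_stroke_model(g$cohort, free = "nu0N",
                         fixed = list(gamma = 0.12, nu1 = 1.3),
                         n_starts = 3, seed = 11)
  f2 <- fit_stroke_model(g$cohort, free = "nu0N",
                         fixed = list(gamma = 0.12, nu1 = 1.3),
                         n_starts = 3, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$minus2logl, f2$minus2logl)
})

test_that("anova orders nested fits and computes the LRT", {
  g <- small_synth()
  co <- g$cohort
  f0 <- fit_stroke_model(co, free = character(0),
                         fixed = list(nu0N = 4.5, gamma = 0.12,
                                      nu1 = 1.3), n_starts = 1)
  f1 <- fit_stroke_model(co, free = "nu0N",
                         fixed = list(gamma = 0.12, nu1 = 1.3),
                         n_starts = 1, seed = 2)
  tab <- anova(f0, f1)
  expect_equal(tab$df[2], 1)
  expect_gte(tab$delta_dev[2], -1e-6)
  expect_true(tab$p_value[2] >= 0 && tab$p_value[2] <= 1)
})

test_that("the target scan attributes a late-stage effect to nu2", {
  truth <- mechanistic_model(
    reference_fit_rates(),
    modifiers = list(covariate_modifier(
      "nu2", "blood_pressure",
      c(normal = 1, hypertensive = 2.5, unknown = 1))))
  co <- generate_cohort(cohort_design(2500, truth, seed = 77))$cohort
  tab <- scan_risk_factor_targets(
    co, "blood_pressure", targets = c("nu0N", "gamma", "nu1", "nu2"),
    free = "nu0N", fixed = list(gamma = 0.12, nu1 = 1.3),
    n_starts = 1, seed = 5)
  expect_equal(nrow(tab), 4)
  # a modifier on any single rate can partially mimic the effect, but the
  # deviance gain must be genuine for all candidates
  expect_true(all(tab$delta_dev < 0, na.rm = TRUE))
  # nu2 (or the strongly confounded nu1 route) explains it best; gamma and
  # nu0N act too early in progression to win
  expect_true(tab$parameter[1] %in% c("nu2", "nu1"))
  # identical categories cannot improve the fit beyond optimizer noise
  co2 <- co
  co2$workers$blood_pressure <- "normal"
  tab2 <- scan_risk_factor_targets(
    co2, "blood_pressure", targets = c("nu2"),
    free = "nu0N", fixed = list(gamma = 0.12, nu1 = 1.3),
    n_starts = 1, seed = 5)
  expect_lt(abs(tab2$delta_dev[1]), 0.05)
})

test_that("empirical fit detects a strong generated dose effect", {
  emp_truth <- empirical_model(intercept = -5.2,
                               age_slopes = c(0.085, 0, 0),
                               err_lambda = 1.0, err_mu = Inf)
  co <- generate_cohort(cohort_design(1200, emp_truth, seed = 19))$cohort
  f0 <- fit_stroke_model(co, model = "empirical", n_starts = 1, seed = 4)
  f1 <- fit_stroke_model(co, model = "empirical", err = TRUE,
                         err_mu = Inf, n_starts = 1, seed = 4)
  expect_lt(f1$minus2logl, f0$minus2logl)
  tab <- anova(f0, f1)
  expect_lt(tab$p_value[2], 0.05)
  expect_gt(coef(f1)[["lambda"]], 0)
})

test_that("predict and plot methods return the fitted curves", {
  g <- small_synth()
  fit <- fit_stroke_model(g$cohort, free = "nu0N",
                          fixed = list(gamma = 0.12, nu1 = 1.3),
                          n_starts = 1, seed = 1)
  grid <- predict(fit, ages = c(20, 50, 80))
  expect_s3_class(grid, "survival_grid")
  expect_true(all(diff(grid$S) < 0))
  pdf(NULL)
  on.exit(dev.off())
  out <- plot(fit, ages = c(20, 50, 80))
  expect_s3_class(out, "survival_grid")
})

test_that("dose-modified likelihoods are exact and the mode scan runs", {
  g <- small_synth()
  co <- g$cohort
  sub <- co
  sub$workers <- sub$workers[1:12, ]
  sub$doses <- sub$doses[sub$doses$id %in% sub$workers$id, ]
  model <- mechanistic_model(reference_fit_rates(),
                             dose_resp = dose_response(
                               "nu2", "cumulative_dose", 0.5))
  dev_fast <- cohort_deviance(sub, model)
  # brute force: per-worker fine survival grids through the same timeline
  hist <- atheromod:::dose_histories(sub)
  ll <- 0
  for (i in seq_len(nrow(sub$workers))) {
    w <- sub$workers[i, ]
    tl <- atheromod:::stratum_timeline(
      model, as.list(w[c("smoking", "blood_pressure", "graduation")]),
      hist[[w$id]])
    gr <- stroke_hazard_survival(tl, seq(floor(w$age_in),
                                         ceiling(w$age_out), by = 0.25),
                                 hazard_method = if (is_homog <-
                                   atheromod:::is_homogeneous(tl))
                                   "auto" else "fd")
    ll <- ll + individual_loglik(list(age_in = w$age_in,
                                      age_out = w$age_out,
                                      event = w$event), gr)
  }
  expect_equal(dev_fast, -2 * ll, tolerance = 1e-4)
  # a dose response must change the deviance relative to the base model
  expect_false(isTRUE(all.equal(
    dev_fast, cohort_deviance(sub, mechanistic_model(
      reference_fit_rates())))))
  # mode scan on a null cohort: both modes fit, neither can improve much
  sub2 <- co
  sub2$workers <- sub2$workers[1:30, ]
  sub2$doses <- sub2$doses[sub2$doses$id %in% sub2$workers$id, ]
  tab <- scan_dose_response(sub2, "nu2", free = character(0),
                            fixed = list(nu0N = 4.5, gamma = 0.12,
                                         nu1 = 1.3),
                            n_starts = 1, seed = 2)
  expect_setequal(tab$mode, c("cumulative_dose", "annual_dose_rate"))
  expect_true(all(is.finite(tab$deviance)))
  # with no generated dose effect the gain is at most chi-square noise
  expect_true(all(tab$delta_dev > -8))
  expect_true(all(tab$delta_dev < 0.5))
})
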