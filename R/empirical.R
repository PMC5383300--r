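# Empirical (descriptive) baseline model: log-linear hazard with
# piecewise-linear age and calendar-year terms, multiplicative covariate
# factors, and an excess-relative-risk radiation term restricted to ages
# below a cutoff mu.
#
# log h(a, y) = b0 + s1 (a - 60) + s2 (a - 40)_+ + s3 (a - 60)_+
#             + c1 (y - 1970) + c2 (y - k_c1)_+ + c3 (y - k_c2)_+
#             + sum log covariate factors
# h is then multiplied by (1 + lambda d) for ages below mu.
# The calendar term is linear already before its first knot (c1 is global).
# Knot locations are configuration values; the parameter counts (3 age,
# 3 calendar) follow the descriptive-model convention.

#' Empirical baseline hazard model
#'
#' @param intercept Log hazard at age 60, calendar year 1970, reference
#'   categories, zero dose.
#' @param age_slopes Length-3: base slope in age and slope changes at the
#'   two age knots (per year).
#' @param cal_slopes Length-3: base slope in calendar year (applies already
#'   before the first knot) and slope changes at the two calendar knots.
#' @param age_knots,cal_knots Knot locations (defaults 40/60 years and
#'   1970/1990).
#' @param covariate_factors Named list: covariate -> named vector of
#'   positive multiplicative factors per category (reference 1).
#' @param err_lambda Excess relative risk per Gy (cumulative dose).
#' @param err_mu Age cutoff in years; dose acts only below it
#'   (\code{Inf}: age-independent excess relative risk).
#' @return An object of class \code{empirical_model}.
#' @export
empirical_model <- function(intercept = -6, age_slopes = c(0.08, 0, 0),
                            cal_slopes = c(0, 0, 0),
                            age_knots = c(40, 60),
                            cal_knots = c(1970, 1990),
                            covariate_factors = list(),
                            err_lambda = 0, err_mu = Inf) {
  stopifnot(length(age_slopes) == 3, length(cal_slopes) == 3,
            length(age_knots) == 2, length(cal_knots) == 2)
  if (err_mu <= 0) stopf("'err_mu' must be positive")
  for (cv in names(covariate_factors)) {
    f <- covariate_factors[[cv]]
    if (any(f <= 0)) stopf("covariate factors must be > 0")
  }
  structure(list(intercept = intercept, age_slopes = age_slopes,
                 cal_slopes = cal_slopes, age_knots = age_knots,
                 cal_knots = cal_knots,
                 covariate_factors = covariate_factors,
                 err_lambda = err_lambda, err_mu = err_mu),
            class = "empirical_model")
}

emp_log_baseline <- function(model, age, calendar_year) {
  s <- model$age_slopes; k <- model$age_knots
  cc <- model$cal_slopes; kc <- model$cal_knots
  model$intercept +
    s[1] * (age - 60) + s[2] * pmax(age - k[1], 0) +
    s[3] * pmax(age - k[2], 0) +
    cc[1] * (calendar_year - 1970) + cc[2] * pmax(calendar_year - kc[1], 0) +
    cc[3] * pmax(calendar_year - kc[2], 0)
}

emp_log_factors <- function(model, covariates) {
  tot <- 0
  for (cv in names(model$covariate_factors)) {
    cat_ <- covariates[[cv]]
    if (is.null(cat_))
      stopf("covariates lack '%s' needed by the empirical model", cv)
    f <- model$covariate_factors[[cv]]
    if (!cat_ %in% names(f))
      stopf("category '%s' not defined for empirical factor on %s", cat_, cv)
    tot <- tot + log(f[[cat_]])
  }
  tot
}

#' Evaluate the empirical hazard
#'
#' @param model An \code{\link{empirical_model}}.
#' @param age Age in years (vectorized).
#' @param calendar_year Calendar year (vectorized or scalar).
#' @param covariates Named list/vector, covariate -> category.
#' @param cumulative_dose Cumulative dose in Gy (vectorized or scalar).
#' @return Hazard per year.
#' @export
empirical_hazard <- function(model, age, calendar_year = 1970,
                             covariates = list(), cumulative_dose = 0) {
  base <- exp(emp_log_baseline(model, age, calendar_year) +
                emp_log_factors(model, covariates))
  fac <- 1 + model$err_lambda * cumulative_dose * (age < model$err_mu)
  if (any(fac <= 0))
    stopf("invalid parameterization: ERR factor <= 0")
  base * fac
}

#' Excess-relative-risk age profile of the empirical model
#'
#' The relative risk for an exposed versus unexposed subject is the
#' constant \eqn{1 + \lambda d} below the age cutoff \eqn{\mu} and exactly
#' 1 at and above it: by construction, hazard-factor models have an
#' age-independent relative risk (contrast with
#' \code{\link{relative_risk}} for the mechanistic model).
#'
#' @param model An \code{\link{empirical_model}}.
#' @param ages Age grid, years.
#' @param dose Cumulative dose, Gy.
#' @return data.frame with columns \code{age}, \code{rr}.
#' @export
err_age_profile <- function(model, ages, dose) {
  check_number(dose, "dose", min = 0)
  rr <- ifelse(ages < model$err_mu, 1 + model$err_lambda * dose, 1)
  if (any(rr <= 0)) stopf("ERR factor <= 0")
  data.frame(age = ages, rr = rr)
}

# Exact integral of the empirical hazard over [a_from, a_to] for one
# worker. Segments split at integer ages (calendar year and cumulative
# dose change annually), at the age knots and at mu; within a segment the
# log hazard is linear in age and the ERR factor is constant.
emp_cumhaz <- function(model, birth_year, covariates, history,
                       a_from, a_to) {
  if (a_to <= a_from) return(0)
  cuts <- sort(unique(c(a_from, a_to,
                        seq(ceiling(a_from), floor(a_to)),
                        model$age_knots, model$err_mu)))
  cuts <- cuts[cuts >= a_from & cuts <= a_to & is.finite(cuts)]
  x1 <- cuts[-length(cuts)]; x2 <- cuts[-1]
  year <- birth_year + floor(x1 + 1e-9)
  d <- cumulative_dose_at(history, x1 + 1e-9)
  lf <- emp_log_factors(model, covariates)
  L1 <- emp_log_baseline(model, x1, year) + lf
  slope <- model$age_slopes[1] +
    model$age_slopes[2] * (x1 + 1e-9 > model$age_knots[1]) +
    model$age_slopes[3] * (x1 + 1e-9 > model$age_knots[2])
  fac <- 1 + model$err_lambda * d * (x1 + 1e-9 < model$err_mu)
  if (any(fac <= 0)) stopf("invalid parameterization: ERR factor <= 0")
  width <- x2 - x1
  piece <- ifelse(abs(slope) < 1e-12,
                  exp(L1) * width,
                  exp(L1) * (exp(slope * width) - 1) / slope)
  sum(fac * piece)
}

#' Survival grid implied by the empirical model for one worker
#'
#' \eqn{S(a) = \exp(-\int_{a_{in}}^{a} h)}, normalized to 1 at the start
#' of follow-up, on the requested age grid; the integral is exact for the
#' piecewise log-linear hazard. The grid plugs into the same
#' individual-likelihood machinery as the mechanistic survival grid.
#'
#' @param model An \code{\link{empirical_model}}.
#' @param record List/row with \code{birth_year}, covariate categories and
#'   (optionally) a dose history as returned by the cohort accessors.
#' @param grid Ascending ages covering the follow-up window.
#' @return A \code{survival_grid} data frame (columns age, S, h).
#' @export
empirical_survival <- function(model, record, grid) {
  history <- record$history %||%
    list(ages = numeric(0), rate = numeric(0), cum = numeric(0))
  covs <- record[intersect(names(covariate_levels), names(record))]
  a0 <- grid[1]
  H <- cumsum(c(0, vapply(seq_along(grid)[-1], function(i)
    emp_cumhaz(model, record$birth_year, covs, history,
               grid[i - 1], grid[i]), 0)))
  year <- record$birth_year + floor(grid)
  d <- cumulative_dose_at(history, grid + 1e-9)
  h <- empirical_hazard(model, grid, year, covs, d)
  new_survival_grid(grid, exp(-H), h, t_lag = 0)
}

# --- vectorized machinery for fitting and generation ---------------------

# Segment table for a set of workers: [a_from_i, a_to_i] split at integer
# ages (calendar years, annual doses and the integer spline knots / ERR
# cutoff all change there). Columns: worker index w, x1, x2, year, d
# (cumulative dose at segment start).
emp_worker_prep <- function(workers, histories, a_from, a_to) {
  n <- nrow(workers)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    cuts <- unique(c(a_from[i],
                     seq2(ceiling(a_from[i] + 1e-9),
                          floor(a_to[i] - 1e-9)),
                     a_to[i]))
    segs[[i]] <- cuts
  }
  n_seg <- vapply(segs, length, 0L) - 1L
  w <- rep(seq_len(n), n_seg)
  x1 <- unlist(lapply(segs, function(cc) cc[-length(cc)]))
  x2 <- unlist(lapply(segs, function(cc) cc[-1]))
  d <- numeric(length(x1))
  ids <- workers$id
  for (i in which(vapply(histories[ids], function(h)
    length(h$ages) > 0, TRUE))) {
    sel <- which(w == i)
    d[sel] <- cumulative_dose_at(histories[[ids[i]]], x1[sel] + 1e-9)
  }
  list(w = w, x1 = x1, x2 = x2, width = x2 - x1,
       year = workers$birth_year[w] + floor(x1 + 1e-9), d = d, n = n)
}

seq2 <- function(from, to) if (from > to) numeric(0) else seq(from, to)

# Per-worker sum of log covariate factors under a model.
emp_logfac <- function(model, workers) {
  lf <- numeric(nrow(workers))
  for (cv in names(model$covariate_factors)) {
    f <- model$covariate_factors[[cv]]
    lf <- lf + log(unname(f[workers[[cv]]]))
  }
  lf
}

# Exact per-segment integrals of the hazard; returns NULL if the ERR
# factor is non-positive anywhere (infeasible parameterization).
emp_pieces <- function(model, prep, logfac) {
  L1 <- emp_log_baseline(model, prep$x1, prep$year) + logfac[prep$w]
  s <- model$age_slopes
  slope <- s[1] + s[2] * (prep$x1 + 1e-9 > model$age_knots[1]) +
    s[3] * (prep$x1 + 1e-9 > model$age_knots[2])
  fac <- 1 + model$err_lambda * prep$d * (prep$x1 + 1e-9 < model$err_mu)
  if (any(fac <= 0)) return(NULL)
  core <- ifelse(abs(slope) < 1e-12, prep$width,
                 expm1(slope * prep$width) / slope)
  list(piece = fac * exp(L1) * core, L1 = L1, slope = slope, fac = fac)
}
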