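# Bounded maximum-likelihood fitting of the mechanistic and empirical
# models, profile-likelihood intervals and model-selection scans.
#
# The optimizer is a bounded quasi-Newton (stats::nlminb) with seeded
# multi-start; infeasible points (beta < 0, non-positive dose factor,
# zero-hazard case) repel with a large finite deviance. Equivalence to
# other minimizers is judged by the achieved deviance, not by optimizer
# identity.

BIG_DEV <- 1e10

new_parspec <- function() {
  data.frame(name = character(), lower = numeric(), upper = numeric(),
             start = numeric(), value = numeric(), free = logical(),
             stringsAsFactors = FALSE)
}

add_par <- function(ps, name, lower, upper, start, value = start,
                    free = TRUE) {
  rbind(ps, data.frame(name = name, lower = lower, upper = upper,
                       start = start, value = value, free = free,
                       stringsAsFactors = FALSE))
}

parspec_mechanistic <- function(free, fixed, bounds, age_laws, modifiers,
                                dose_resp, hazard_factors) {
  ps <- new_parspec()
  b <- bounds
  for (nm in c("nu0N", "gamma", "nu1")) {
    bi <- b[b$name == nm, ]
    if (nm %in% free)
      ps <- add_par(ps, nm, bi$lower, bi$upper, bi$start)
    else
      ps <- add_par(ps, nm, -Inf, Inf, fixed[[nm]], fixed[[nm]],
                    free = FALSE)
  }
  for (nm in c("alpha", "nu2", "t_lag"))
    ps <- add_par(ps, nm, -Inf, Inf, fixed[[nm]], fixed[[nm]],
                  free = FALSE)
  for (law in age_laws) {
    if (inherits(law, "age_power_law")) next  # fixed law
    ps <- add_par(ps, paste0("psi_", law$parameter), -1, 1, 0)
  }
  for (mod in modifiers) {
    if (inherits(mod, "covariate_modifier")) next  # fixed modifier
    cats <- mod$categories %||% covariate_levels[[mod$covariate]][-1]
    for (cat_ in cats)
      ps <- add_par(ps, paste("mod", mod$parameter, mod$covariate, cat_,
                              sep = "."),
                    0.05, 20, 1)
  }
  if (!is.null(dose_resp) && !inherits(dose_resp, "dose_response"))
    ps <- add_par(ps, "lambda", -0.45, 20, 0)
  if (!is.null(hazard_factors)) {
    if (isTRUE(hazard_factors$calendar))
      for (k in 1:3)
        ps <- add_par(ps, paste0("cal", k), -0.2, 0.2, 0)
    for (cv in hazard_factors$covariates)
      for (cat_ in covariate_levels[[cv]][-1])
        ps <- add_par(ps, paste("hf", cv, cat_, sep = "."), -3, 3, 0)
  }
  ps
}

make_mechanistic_builder <- function(age_laws, modifiers, dose_resp,
                                     hazard_factors, grid_step, max_age) {
  function(theta) {
    rates <- rate_set(nu0N = theta[["nu0N"]], gamma = theta[["gamma"]],
                      nu1 = theta[["nu1"]], alpha = theta[["alpha"]],
                      nu2 = theta[["nu2"]], t_lag = theta[["t_lag"]])
    laws <- lapply(age_laws, function(law) {
      if (inherits(law, "age_power_law")) law
      else age_power_law(law$parameter,
                         psi = theta[[paste0("psi_", law$parameter)]])
    })
    mods <- lapply(modifiers, function(mod) {
      if (inherits(mod, "covariate_modifier")) mod
      else {
        lev <- covariate_levels[[mod$covariate]]
        cats <- mod$categories %||% lev[-1]
        mult <- stats::setNames(rep(1, length(lev)), lev)
        for (cat_ in cats)
          mult[[cat_]] <- theta[[paste("mod", mod$parameter,
                                       mod$covariate, cat_, sep = ".")]]
        covariate_modifier(mod$parameter, mod$covariate, mult)
      }
    })
    dr <- if (is.null(dose_resp)) NULL
    else if (inherits(dose_resp, "dose_response")) dose_resp
    else dose_response(dose_resp$parameter, dose_resp$mode,
                       theta[["lambda"]])
    hf <- NULL
    if (!is.null(hazard_factors)) {
      hf <- list()
      if (isTRUE(hazard_factors$calendar))
        hf$cal_slopes <- c(theta[["cal1"]], theta[["cal2"]],
                           theta[["cal3"]])
      hf$covariates <- lapply(
        stats::setNames(hazard_factors$covariates,
                        hazard_factors$covariates),
        function(cv) {
          lev <- covariate_levels[[cv]]
          f <- c(1, exp(vapply(lev[-1], function(cat_)
            theta[[paste("hf", cv, cat_, sep = ".")]], 0)))
          names(f) <- lev
          f
        })
      if (!length(hf$covariates)) hf$covariates <- NULL
    }
    mechanistic_model(rates, laws, mods, dr, hf, grid_step, max_age)
  }
}

parspec_empirical <- function(emp_covariates, err, err_mu) {
  ps <- new_parspec()
  ps <- add_par(ps, "intercept", -15, 0, -6)
  ps <- add_par(ps, "age_s1", -0.5, 0.5, 0.08)
  ps <- add_par(ps, "age_s2", -0.5, 0.5, 0)
  ps <- add_par(ps, "age_s3", -0.5, 0.5, 0)
  for (k in 1:3) ps <- add_par(ps, paste0("cal_s", k), -0.2, 0.2, 0)
  for (cv in emp_covariates)
    for (cat_ in covariate_levels[[cv]][-1])
      ps <- add_par(ps, paste("emp", cv, cat_, sep = "."), -3, 3, 0)
  if (err) ps <- add_par(ps, "lambda", -0.45, 20, 0)
  ps <- add_par(ps, "err_mu", -Inf, Inf, err_mu, err_mu, free = FALSE)
  ps
}

make_empirical_builder <- function(emp_covariates, err, age_knots,
                                   cal_knots) {
  function(theta) {
    factors <- lapply(
      stats::setNames(emp_covariates, emp_covariates),
      function(cv) {
        lev <- covariate_levels[[cv]]
        f <- c(1, exp(vapply(lev[-1], function(cat_)
          theta[[paste("emp", cv, cat_, sep = ".")]], 0)))
        names(f) <- lev
        f
      })
    empirical_model(
      intercept = theta[["intercept"]],
      age_slopes = c(theta[["age_s1"]], theta[["age_s2"]],
                     theta[["age_s3"]]),
      cal_slopes = c(theta[["cal_s1"]], theta[["cal_s2"]],
                     theta[["cal_s3"]]),
      age_knots = age_knots, cal_knots = cal_knots,
      covariate_factors = factors,
      err_lambda = if (err) theta[["lambda"]] else 0,
      err_mu = theta[["err_mu"]])
  }
}

#' Fit the mechanistic or empirical stroke model to a cohort
#'
#' Maximizes the individual likelihood
#' \eqn{l = \prod_i S(a_{i,out})/S(a_{i,in}) \, h(a_{i,out})^{\delta_i}}
#' over the free parameters by bounded local minimization of the deviance
#' \eqn{-2\ln l} from several seeded start points, returning the best
#' minimum found.
#'
#' @param cohort A \code{\link{stroke_cohort}}.
#' @param model \code{"mechanistic"} or \code{"empirical"}.
#' @param free Free biological parameters (mechanistic; subset of
#'   \code{nu0N}, \code{gamma}, \code{nu1}).
#' @param fixed Named list of fixed parameter values; defaults fix
#'   \code{alpha = 12}, \code{nu2 = 1e-7}, \code{t_lag = 10} (and supply
#'   fallback values for non-free biological parameters).
#' @param bounds data.frame like \code{\link{default_rate_bounds}}.
#' @param age_laws List; each element an \code{\link{age_power_law}} (held
#'   fixed) or \code{list(parameter =)} to estimate its exponent.
#' @param modifiers List; each element a \code{\link{covariate_modifier}}
#'   (fixed) or \code{list(parameter =, covariate =)} to estimate one
#'   multiplier per non-reference category (or per category listed in an
#'   optional \code{categories} element; the rest stay at 1).
#' @param dose_resp A \code{\link{dose_response}} (fixed) or
#'   \code{list(parameter =, mode =)} to estimate the slope.
#' @param hazard_factors Mechanistic surrogate factors:
#'   \code{list(calendar = TRUE, covariates = c("graduation"))}.
#' @param emp_covariates Covariates entering the empirical model as
#'   multiplicative hazard factors.
#' @param err Include the excess-relative-risk dose term (empirical).
#' @param err_mu Age cutoff for the radiation effect, years (empirical;
#'   \code{Inf} for an age-independent excess relative risk).
#' @param age_knots,cal_knots Spline knots of the empirical baseline.
#' @param reference_deviance Optional reference deviance \code{dev0};
#'   \code{delta_dev = minus2logl - dev0}.
#' @param n_starts Number of optimizer starts (first from the default
#'   start values, the rest drawn uniformly within bounds).
#' @param seed Integer seed for the start draws.
#' @param grid_step Likelihood age-grid step, years.
#' @param max_age Solver coverage, years; defaults to the cohort's oldest
#'   exit age plus 5.
#' @param control Passed to \code{\link[stats]{nlminb}}.
#' @return An object of class \code{stroke_fit}: estimates, deviance,
#'   convergence diagnostics, and the fitted model configuration.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{logLik},
#'   \code{confint} (profile likelihood), \code{predict}, \code{plot},
#'   \code{anova}.
#' @export
fit_stroke_model <- function(cohort,
                             model = c("mechanistic", "empirical"),
                             free = c("nu0N", "gamma", "nu1"),
                             fixed = list(), bounds = default_rate_bounds(),
                             age_laws = list(), modifiers = list(),
                             dose_resp = NULL, hazard_factors = NULL,
                             emp_covariates = character(), err = FALSE,
                             err_mu = Inf, age_knots = c(40, 60),
                             cal_knots = c(1970, 1990),
                             reference_deviance = NULL, n_starts = 5,
                             seed = 1, grid_step = 1, max_age = NULL,
                             control = list()) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  model <- match.arg(model)
  if (is.null(max_age))
    max_age <- ceiling(max(cohort$workers$age_out)) + 5
  if (model == "mechanistic") {
    fixed <- utils::modifyList(
      list(alpha = 12, nu2 = 1e-7, t_lag = 10, nu0N = 4.5, gamma = 0.12,
           nu1 = 1.3), fixed)
    free <- if (length(free))
      match.arg(free, c("nu0N", "gamma", "nu1"), several.ok = TRUE)
    else character(0)
    ps <- parspec_mechanistic(free, fixed, bounds, age_laws, modifiers,
                              dose_resp, hazard_factors)
    build <- make_mechanistic_builder(age_laws, modifiers, dose_resp,
                                      hazard_factors, grid_step, max_age)
  } else {
    ps <- parspec_empirical(emp_covariates, err, err_mu)
    build <- make_empirical_builder(emp_covariates, err, age_knots,
                                    cal_knots)
  }
  res <- optimize_deviance(cohort, ps, build, n_starts, seed, control)
  est <- res$theta[ps$free]
  fit <- structure(list(
    model_kind = model, parspec = ps, estimates = est,
    minus2logl = res$deviance,
    reference_deviance = reference_deviance,
    delta_dev = if (!is.null(reference_deviance))
      res$deviance - reference_deviance else NA_real_,
    converged = res$converged, n_evaluations = res$n_evaluations,
    n_starts = n_starts, seed = seed,
    model = build(res$theta), build = build, cohort = cohort,
    n_workers = nrow(cohort$workers),
    person_years = person_years(cohort), n_cases = n_cases(cohort)),
    class = "stroke_fit")
  fit
}

# Multi-start bounded minimization of the cohort deviance.
optimize_deviance <- function(cohort, ps, build, n_starts, seed, control,
                              warm = NULL, polish = TRUE) {
  free_idx <- which(ps$free)
  theta_full <- stats::setNames(ps$value, ps$name)
  n_eval <- 0L
  objective <- function(x) {
    th <- theta_full
    th[free_idx] <- x
    n_eval <<- n_eval + 1L
    dev <- tryCatch(cohort_deviance(cohort, build(th)),
                    error = function(e) Inf)
    if (!is.finite(dev)) BIG_DEV else dev
  }
  if (!length(free_idx)) {
    dev <- objective(numeric(0))
    return(list(theta = theta_full, deviance = dev, converged = TRUE,
                n_evaluations = n_eval))
  }
  lower <- ps$lower[free_idx]; upper <- ps$upper[free_idx]
  # optimize in box-scaled coordinates: the free parameters span very
  # different ranges (e.g. nu0N in [1,10] vs gamma in [0.1,0.3]) and the
  # deviance surface has a correlated ridge; scaling conditions the
  # finite-difference quasi-Newton steps
  span <- upper - lower
  to_z <- function(x) (x - lower) / span
  from_z <- function(z) lower + z * span
  obj_z <- function(z) objective(from_z(z))
  starts <- list(if (is.null(warm)) ps$start[free_idx] else warm)
  if (n_starts > 1) {
    set.seed(as.integer(derive_seed(seed, 1)))
    for (k in seq_len(n_starts - 1))
      starts[[k + 1]] <- stats::runif(length(free_idx), lower, upper)
  }
  best <- NULL
  ctrl <- utils::modifyList(list(rel.tol = 1e-9), control)
  for (st in starts) {
    opt <- stats::nlminb(to_z(st), obj_z, lower = rep(0, length(span)),
                         upper = rep(1, length(span)), control = ctrl)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  improved <- 0
  if (polish) {
    # the deviance surface has long, gently curved ridges on which
    # finite-difference quasi-Newton steps stall; alternate a
    # derivative-free simplex stage with nlminb restarts until the
    # objective stops improving
    for (k in 1:3) {
      if (length(free_idx) > 1) {
        nm <- stats::optim(pmin(pmax(best$par, 1e-6), 1 - 1e-6), obj_z,
                           method = "Nelder-Mead",
                           control = list(maxit = 150 * length(free_idx),
                                          reltol = 1e-10))
        if (nm$value < best$objective)
          best <- list(par = nm$par, objective = nm$value,
                       convergence = best$convergence)
      } else {
        br <- stats::optimize(obj_z, c(0, 1), tol = 1e-7)
        if (br$objective < best$objective)
          best <- list(par = br$minimum, objective = br$objective,
                       convergence = 0)
      }
      repolish <- stats::nlminb(best$par, obj_z,
                                lower = rep(0, length(span)),
                                upper = rep(1, length(span)),
                                control = ctrl)
      improved <- best$objective - repolish$objective
      if (repolish$objective <= best$objective) best <- repolish
      if (improved < 1e-3) break
    }
  } else if (length(free_idx) > 1) {
    # profiled evaluations: a short simplex pass keeps the nuisance
    # optimization honest at modest cost
    nm <- stats::optim(pmin(pmax(best$par, 1e-6), 1 - 1e-6), obj_z,
                       method = "Nelder-Mead",
                       control = list(maxit = 60 * length(free_idx),
                                      reltol = 1e-9))
    if (nm$value < best$objective)
      best <- list(par = nm$par, objective = nm$value,
                   convergence = 0)
  }
  theta_full[free_idx] <- from_z(best$par)
  list(theta = theta_full, deviance = best$objective,
       converged = (best$convergence == 0 || improved < 1e-3) &&
         best$objective < BIG_DEV / 2,
       n_evaluations = n_eval)
}

#' @export
print.stroke_fit <- function(x, ...) {
  cat(sprintf("%s stroke model fit\n",
              if (x$model_kind == "mechanistic") "Mechanistic"
              else "Empirical"))
  cat(sprintf("  cohort: %d workers, %.0f person-years, %d cases\n",
              x$n_workers, x$person_years, x$n_cases))
  cat(sprintf("  deviance (-2 log L): %.3f%s\n", x$minus2logl,
              if (!is.na(x$delta_dev))
                sprintf("  (delta vs reference: %.3f)", x$delta_dev)
              else ""))
  if (length(x$estimates)) {
    cat("  estimates:\n")
    print(round(x$estimates, 5))
  }
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.stroke_fit <- function(object, ...) object$estimates

#' @export
logLik.stroke_fit <- function(object, ...) {
  val <- -object$minus2logl / 2
  attr(val, "df") <- sum(object$parspec$free)
  class(val) <- "logLik"
  val
}

#' @export
summary.stroke_fit <- function(object, level = 0.95, profile = FALSE,
                               ...) {
  ci <- if (profile) stats::confint(object, level = level) else NULL
  out <- list(fit = object, ci = ci, level = level)
  class(out) <- "summary.stroke_fit"
  out
}

#' @export
print.summary.stroke_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ci)) {
    cat(sprintf("  %g%% profile-likelihood intervals:\n", 100 * x$level))
    print(round(x$ci, 5))
  }
  invisible(x)
}

# Profiled deviance at a pinned value of one free parameter.
profiled_deviance <- function(fit, parameter, value, control = list(),
                              warm = NULL) {
  ps <- fit$parspec
  i <- match(parameter, ps$name)
  ps$free[i] <- FALSE
  ps$value[i] <- value
  est <- fit$estimates[setdiff(names(fit$estimates), parameter)]
  if (!is.null(warm)) est[names(warm)] <- warm
  full <- stats::setNames(ps$value, ps$name)
  full[names(fit$estimates)] <- fit$estimates
  full[parameter] <- value
  ps$value <- unname(full[ps$name])
  res <- optimize_deviance(fit$cohort, ps, fit$build, n_starts = 1,
                           seed = fit$seed, control = control,
                           warm = unname(est[ps$name[ps$free]]),
                           polish = FALSE)
  out <- res$deviance
  attr(out, "nuisance") <- res$theta[ps$name[ps$free]]
  out
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Interval bounds where the profiled deviance (re-maximizing all other
#' free parameters) exceeds the minimum deviance by the \eqn{\chi^2_1}
#' quantile \eqn{2 \times 1.92 = 3.84} at the 95\% level, found by
#' bracketed root search. Bounds truncated by the box constraints are
#' flagged as boundary-censored.
#'
#' @param fit A converged \code{\link{fit_stroke_model}} fit.
#' @param parameter Name of a free parameter.
#' @param level Confidence level.
#' @return List with \code{lower}, \code{upper},
#'   \code{lower_censored}, \code{upper_censored}.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  ps <- fit$parspec
  i <- match(parameter, ps$name)
  if (is.na(i) || !ps$free[i]) stopf("'%s' is not a free parameter",
                                     parameter)
  target <- fit$minus2logl + stats::qchisq(level, df = 1)
  est <- fit$estimates[[parameter]]
  bound <- c(lower = ps$lower[i], upper = ps$upper[i])
  out <- list(lower = NA_real_, upper = NA_real_,
              lower_censored = FALSE, upper_censored = FALSE)
  for (side in c("lower", "upper")) {
    b <- bound[[side]]
    warm <- NULL
    f <- function(x) {
      r <- profiled_deviance(fit, parameter, x,
                             control = list(rel.tol = 1e-7), warm = warm)
      warm <<- attr(r, "nuisance")
      as.numeric(r) - target
    }
    fracs <- c(0.25, 0.55, 1)
    x_prev <- est; f_prev <- fit$minus2logl - target
    hit <- FALSE
    for (fr in fracs) {
      x <- est + fr * (b - est)
      fx <- f(x)
      if (fx > 0) {
        root <- stats::uniroot(f, lower = min(x_prev, x),
                               upper = max(x_prev, x),
                               f.lower = if (x_prev < x) f_prev else fx,
                               f.upper = if (x_prev < x) fx else f_prev,
                               tol = max(5e-4 * abs(est), 2e-4))
        out[[side]] <- root$root
        hit <- TRUE
        break
      }
      x_prev <- x; f_prev <- fx
    }
    if (!hit) {
      out[[side]] <- b
      out[[paste0(side, "_censored")]] <- TRUE
    }
  }
  out
}

#' @export
confint.stroke_fit <- function(object, parm = NULL, level = 0.95, ...) {
  free_names <- object$parspec$name[object$parspec$free]
  parm <- parm %||% free_names
  out <- t(vapply(parm, function(p) {
    ci <- profile_ci(object, p, level)
    c(ci$lower, ci$upper)
  }, c(0, 0)))
  colnames(out) <- sprintf("%g %%",
                           100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
anova.stroke_fit <- function(object, ..., test = TRUE) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2) stopf("need two nested fits for a LRT")
  dfs <- vapply(fits, function(f) sum(f$parspec$free), 0)
  devs <- vapply(fits, `[[`, 0, "minus2logl")
  ord <- order(dfs)
  dfs <- dfs[ord]; devs <- devs[ord]
  delta <- c(NA, -diff(devs))
  ddf <- c(NA, diff(dfs))
  p <- c(NA, mapply(function(dd, k) lrt(dd, 0, k), delta[-1], ddf[-1]))
  data.frame(n_par = dfs, deviance = devs, delta_dev = delta, df = ddf,
             p_value = p)
}

#' @export
predict.stroke_fit <- function(object, ages = 0:100,
                               covariates = list(), history = NULL,
                               ...) {
  covs <- utils::modifyList(
    lapply(covariate_levels, `[`, 1), as.list(covariates))
  if (object$model_kind == "mechanistic") {
    tl <- stratum_timeline(object$model, covs, history)
    grid <- stroke_hazard_survival(tl, ages)
    if (!is.null(object$model$hazard_factors))
      warning("surrogate hazard factors are not applied by predict()")
    grid
  } else {
    rec <- c(list(birth_year = list(...)$birth_year %||% 1930,
                  history = history), covs)
    empirical_survival(object$model, rec, ages)
  }
}

#' @export
plot.stroke_fit <- function(x, ages = seq(20, 90, by = 0.5), ...) {
  grid <- predict(x, ages = ages)
  graphics::plot(grid$age, grid$h, type = "l", xlab = "age (years)",
                 ylab = "stroke hazard (1/year)",
                 main = sprintf("%s model hazard", x$model_kind), ...)
  invisible(grid)
}

#' Scan candidate target rates for a risk-factor effect
#'
#' Refits the mechanistic model once per candidate biological parameter,
#' letting the given covariate multiply that rate, and tabulates the
#' achieved deviances: the model-selection procedure that attributes a risk
#' factor to a step of disease progression.
#'
#' @param cohort A \code{\link{stroke_cohort}}.
#' @param covariate Covariate name present in the cohort.
#' @param targets Candidate parameters (default all five rates).
#' @param ... Passed to \code{\link{fit_stroke_model}} (e.g. \code{free},
#'   \code{fixed}, \code{n_starts}, \code{seed}).
#' @return data.frame sorted by deviance with columns \code{parameter},
#'   \code{deviance}, \code{delta_dev} (vs. the no-modifier fit),
#'   \code{converged}; failed candidates carry NA deviance.
#' @export
scan_risk_factor_targets <- function(cohort, covariate,
                                     targets = c("nu0N", "alpha", "gamma",
                                                 "nu1", "nu2"), ...) {
  if (!covariate %in% names(covariate_levels))
    stopf("unknown covariate '%s'", covariate)
  base <- fit_stroke_model(cohort, ...)
  rows <- lapply(targets, function(tg) {
    ft <- tryCatch(
      fit_stroke_model(cohort,
                       modifiers = list(list(parameter = tg,
                                             covariate = covariate)),
                       ...),
      error = function(e) NULL)
    if (is.null(ft))
      data.frame(parameter = tg, deviance = NA_real_,
                 delta_dev = NA_real_, converged = FALSE)
    else
      data.frame(parameter = tg, deviance = ft$minus2logl,
                 delta_dev = ft$minus2logl - base$minus2logl,
                 converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  out[order(out$deviance), ]
}

#' Compare short-term and persistent radiation action on a rate
#'
#' Refits the mechanistic model once per dose-response mode (annual dose
#' rate versus hitherto accumulated dose) acting on the given biological
#' parameter, with the slope estimated, and tabulates the achieved
#' deviances against the no-dose-response fit.
#'
#' @param cohort A \code{\link{stroke_cohort}} with dose histories.
#' @param parameter Target biological parameter.
#' @param modes Dose-response modes to scan.
#' @param ... Passed to \code{\link{fit_stroke_model}}.
#' @return data.frame sorted by deviance with columns \code{mode},
#'   \code{lambda}, \code{deviance}, \code{delta_dev}, \code{converged}.
#' @export
scan_dose_response <- function(cohort, parameter,
                               modes = c("cumulative_dose",
                                         "annual_dose_rate"), ...) {
  base <- fit_stroke_model(cohort, ...)
  rows <- lapply(modes, function(md) {
    ft <- tryCatch(
      fit_stroke_model(cohort,
                       dose_resp = list(parameter = parameter, mode = md),
                       ...),
      error = function(e) NULL)
    if (is.null(ft))
      data.frame(mode = md, lambda = NA_real_, deviance = NA_real_,
                 delta_dev = NA_real_, converged = FALSE)
    else
      data.frame(mode = md, lambda = ft$estimates[["lambda"]],
                 deviance = ft$minus2logl,
                 delta_dev = ft$minus2logl - base$minus2logl,
                 converged = ft$converged)
  })
  out <- do.call(rbind, rows)
  out[order(out$deviance), ]
}
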