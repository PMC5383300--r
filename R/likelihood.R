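# Individual-likelihood machinery.
#
# Each worker contributes l_i = S(a_out)/S(a_in) * h(a_out)^delta, the
# probability of surviving stroke-free over the observed window and, for a
# case, of the event at the exit age. The equation drops normalization
# constants, which cancel in deviance differences. The cohort deviance is
# -2 sum log l_i; workers sharing a covariate/dose stratum share one
# survival grid (deduplicated by a hash of the realized timeline).

#' Mechanistic cohort model configuration
#'
#' Bundles the base biological rates with the structures that make realized
#' rates depend on age (power laws), categorical covariates (multipliers on
#' a rate) and radiation dose, plus optional multiplicative hazard factors
#' for surrogate variables (calendar year, graduation) that do not carry a
#' biological interpretation. The surrogate treatment multiplies the stroke
#' hazard itself, not a biological rate; this is a descriptive
#' reconstruction, not part of the cell-level model.
#'
#' @param rates Base \code{\link{rate_set}}.
#' @param age_laws List of \code{\link{age_power_law}}s.
#' @param modifiers List of \code{\link{covariate_modifier}}s.
#' @param dose_resp A \code{\link{dose_response}} or NULL.
#' @param hazard_factors Optional list with elements \code{cal_slopes}
#'   (length 3, knots as in \code{\link{empirical_model}}) and
#'   \code{covariates} (named list: covariate -> named vector of positive
#'   factors, reference 1).
#' @param grid_step Likelihood age-grid step, years (default 1; survival is
#'   interpolated log-linearly inside grid intervals).
#' @param max_age Solver coverage, years.
#' @return An object of class \code{mechanistic_model}.
#' @export
mechanistic_model <- function(rates, age_laws = list(), modifiers = list(),
                              dose_resp = NULL, hazard_factors = NULL,
                              grid_step = 1, max_age = 110) {
  stopifnot(inherits(rates, "rate_set"))
  if (inherits(age_laws, "age_power_law")) age_laws <- list(age_laws)
  if (inherits(modifiers, "covariate_modifier"))
    modifiers <- list(modifiers)
  structure(list(rates = rates, age_laws = age_laws, modifiers = modifiers,
                 dose_resp = dose_resp, hazard_factors = hazard_factors,
                 grid_step = grid_step, max_age = max_age),
            class = "mechanistic_model")
}

# Log-linear interpolation of S and linear interpolation of h on a grid.
grid_logS_at <- function(grid, ages)
  stats::approx(grid$age, log(grid$S), xout = ages, rule = 2)$y

grid_h_at <- function(grid, ages)
  stats::approx(grid$age, grid$h, xout = ages, rule = 2)$y

#' Individual log-likelihood contribution
#'
#' \eqn{\ln l_i = \ln S(a_{out}) - \ln S(a_{in}) + \delta \ln h(a_{out})},
#' with \eqn{S} interpolated log-linearly between grid points. A case at an
#' age where the model hazard is zero contributes \code{-Inf} (reported,
#' never silently dropped).
#'
#' @param record List/row with \code{age_in}, \code{age_out}, \code{event}.
#' @param survival A \code{survival_grid} covering the follow-up window.
#' @return Log-likelihood contribution (may be \code{-Inf}).
#' @export
individual_loglik <- function(record, survival) {
  ll <- grid_logS_at(survival, record$age_out) -
    grid_logS_at(survival, record$age_in)
  if (record$event == 1) {
    h <- grid_h_at(survival, record$age_out)
    ll <- ll + if (h > 0) log(h) else -Inf
  }
  ll
}

# --- mechanistic deviance ------------------------------------------------

# Realized timeline for one covariate/dose stratum.
stratum_timeline <- function(model, covs, history = NULL) {
  ctx <- function(age) {
    rate <- 0; cum <- 0
    if (!is.null(history) && length(history$ages)) {
      k <- findInterval(age, history$ages)
      in_year <- k >= 1 && age < history$ages[k] + 1
      rate <- if (in_year) history$rate[k] else 0
      cum <- cumulative_dose_at(history, age)
    }
    parameter_context(age = age, covariates = covs,
                      cumulative_dose = cum, annual_dose_rate = rate)
  }
  has_dose <- !is.null(model$dose_resp) && !is.null(history) &&
    length(history$ages) > 0
  if (length(model$age_laws) == 0 && !has_dose) {
    constant_timeline(evaluate_rates(model$rates, model$age_laws,
                                     model$modifiers, model$dose_resp,
                                     ctx(40)),
                      max_age = model$max_age)
  } else if (length(model$age_laws) == 0) {
    # rates change only where the dose history does: compress the
    # timeline to exposure-year breakpoints (exact for annual doses)
    breaks <- sort(unique(c(0, history$ages,
                            max(history$ages) + 1)))
    breaks <- breaks[breaks < model$max_age]
    parameter_timeline(lapply(c(breaks[-1], model$max_age) / 2 +
                                breaks / 2, function(m)
                                  evaluate_rates(model$rates, list(),
                                                 model$modifiers,
                                                 model$dose_resp, ctx(m))),
                       breakpoints = breaks, max_age = model$max_age)
  } else {
    timeline_from_evaluator(function(a)
      evaluate_rates(model$rates, model$age_laws, model$modifiers,
                     model$dose_resp, ctx(a)),
      max_age = model$max_age, step = 1)
  }
}

# Multiplicative surrogate hazard factor for given calendar years and a
# covariate row.
hazard_factor_at <- function(hf, calendar_year, worker_covs) {
  if (is.null(hf)) return(rep(1, length(calendar_year)))
  lf <- 0
  if (!is.null(hf$cal_slopes)) {
    kc <- hf$cal_knots %||% c(1970, 1990)
    cc <- hf$cal_slopes
    lf <- lf + cc[1] * (calendar_year - 1970) +
      cc[2] * pmax(calendar_year - kc[1], 0) +
      cc[3] * pmax(calendar_year - kc[2], 0)
  }
  for (cv in names(hf$covariates)) {
    f <- hf$covariates[[cv]]
    lf <- lf + log(f[[worker_covs[[cv]]]])
  }
  exp(lf)
}

#' Cohort deviance
#'
#' \eqn{-2 \sum_i \ln l_i} under a mechanistic or empirical model
#' configuration. Workers sharing identical realized parameter timelines
#' share one survival grid. If any case falls at an age with zero model
#' hazard the deviance is \code{+Inf}, with the offending worker ids
#' attached as attribute \code{"bad_records"}.
#'
#' @param cohort A \code{\link{stroke_cohort}}.
#' @param model A \code{\link{mechanistic_model}} or
#'   \code{\link{empirical_model}}.
#' @return Deviance (scalar; \code{+Inf} on zero-hazard cases).
#' @export
cohort_deviance <- function(cohort, model) {
  stopifnot(inherits(cohort, "stroke_cohort"))
  if (inherits(model, "mechanistic_model"))
    mech_deviance(cohort, model)
  else if (inherits(model, "empirical_model"))
    emp_deviance(cohort, model)
  else stopf("'model' must be a mechanistic_model or empirical_model")
}

mech_deviance <- function(cohort, model) {
  w <- cohort$workers
  if (!nrow(w)) return(0)
  grid_ages <- seq(0, model$max_age, by = model$grid_step)
  use_dose <- !is.null(model$dose_resp)
  histories <- if (use_dose || !is.null(model$hazard_factors))
    dose_histories(cohort)
  mod_covs <- unique(vapply(model$modifiers, `[[`, "", "covariate"))
  strat_key <- if (length(mod_covs))
    do.call(paste, c(lapply(mod_covs, function(cv) w[[cv]]), sep = "|"))
  else rep("", nrow(w))
  if (use_dose) {
    hist_key <- vapply(seq_len(nrow(w)), function(i) {
      h <- histories[[w$id[i]]]
      if (!length(h$ages)) "" else
        paste(c(h$ages, signif(h$rate, 12)), collapse = ",")
    }, "")
    strat_key <- paste(strat_key, hist_key, sep = "#")
  }
  grid_keys <- character(0)
  grid_list <- list()
  ll <- numeric(nrow(w))
  bad <- character(0)
  for (key in unique(strat_key)) {
    idx <- which(strat_key == key)
    i0 <- idx[1]
    covs <- as.list(w[i0, names(covariate_levels), drop = FALSE])
    history <- if (use_dose) histories[[w$id[i0]]]
    tl <- stratum_timeline(model, covs, history)
    if (use_dose && !is_homogeneous(tl) &&
        is.null(model$hazard_factors)) {
      # dose-modified timeline: evaluate exactly at this stratum's own
      # entry/exit ages instead of tabulating a full grid
      t_in <- pmax(w$age_in[idx] - tl$t_lag, 0)
      t_out <- pmax(w$age_out[idx] - tl$t_lag, 0)
      sol <- solve_plaque_process(tl, c(t_in, t_out),
                                  hazard_method = "augmented")
      k <- length(idx)
      lli <- log(sol$S[k + seq_len(k)]) - log(sol$S[seq_len(k)])
      ev <- w$event[idx] == 1
      h_out <- sol$h[k + seq_len(k)]
      lli[ev] <- lli[ev] + ifelse(h_out[ev] > 0, log(h_out[ev]), -Inf)
      bad <- c(bad, w$id[idx][!is.finite(lli)])
      ll[idx] <- lli
      next
    }
    tkey <- timeline_key(tl)
    hit <- match(tkey, grid_keys)
    if (is.na(hit)) {
      grid <- stroke_hazard_survival(tl, grid_ages)
      grid_keys <- c(grid_keys, tkey)
      grid_list[[length(grid_keys)]] <- grid
    } else grid <- grid_list[[hit]]
    lnS_out <- grid_logS_at(grid, w$age_out[idx])
    lnS_in <- grid_logS_at(grid, w$age_in[idx])
    h_out <- grid_h_at(grid, w$age_out[idx])
    if (is.null(model$hazard_factors)) {
      lli <- lnS_out - lnS_in
      ev <- w$event[idx] == 1
      lli[ev] <- lli[ev] + ifelse(h_out[ev] > 0, log(h_out[ev]), -Inf)
    } else {
      lli <- vapply(seq_along(idx), function(j) {
        i <- idx[j]
        mech_loglik_factored(model, grid, w[i, ], histories[[w$id[i]]])
      }, 0)
    }
    bad <- c(bad, w$id[idx][!is.finite(lli)])
    ll[idx] <- lli
  }
  if (length(bad)) {
    out <- Inf
    attr(out, "bad_records") <- bad
    return(out)
  }
  -2 * sum(ll)
}

# Worker log-likelihood when surrogate hazard factors are present: the
# cumulative hazard of the stratum grid is scaled year by year by the
# calendar/graduation factor, and the event hazard picks up the factor of
# the exit year.
mech_loglik_factored <- function(model, grid, wrow, history) {
  a_in <- wrow$age_in; a_out <- wrow$age_out
  cuts <- sort(unique(c(a_in, a_out, seq(ceiling(a_in), floor(a_out)))))
  x1 <- cuts[-length(cuts)]; x2 <- cuts[-1]
  years <- wrow$birth_year + floor(x1 + 1e-9)
  covs <- as.list(wrow[names(covariate_levels)])
  f <- hazard_factor_at(model$hazard_factors, years, covs)
  H1 <- -grid_logS_at(grid, x1)
  H2 <- -grid_logS_at(grid, x2)
  ll <- -sum(f * (H2 - H1))
  if (wrow$event == 1) {
    h <- grid_h_at(grid, a_out) * f[length(f)]
    ll <- ll + if (h > 0) log(h) else -Inf
  }
  ll
}

# --- empirical deviance --------------------------------------------------

# Segment tables are cached per cohort (cheap fingerprint) so repeated
# deviance evaluations during optimization only recompute the vectorized
# hazard algebra.
.emp_cache <- new.env(parent = emptyenv())

emp_fingerprint <- function(cohort) {
  w <- cohort$workers
  sprintf("%d|%.8f|%d|%.8f|%.6f", nrow(w), sum(w$age_out), sum(w$event),
          sum(w$age_in), sum(cohort$doses$dose_gy))
}

emp_prep_cached <- function(cohort) {
  key <- emp_fingerprint(cohort)
  prep <- .emp_cache[[key]]
  if (is.null(prep)) {
    w <- cohort$workers
    histories <- dose_histories(cohort)
    prep <- emp_worker_prep(w, histories, w$age_in, w$age_out)
    prep$event <- w$event
    prep$a_out <- w$age_out
    prep$year_out <- w$birth_year + floor(w$age_out - 1e-9)
    prep$d_out <- vapply(seq_len(nrow(w)), function(i)
      cumulative_dose_at(histories[[w$id[i]]], w$age_out[i]), 0)
    prep$workers <- w
    if (length(ls(.emp_cache)) > 8) rm(list = ls(.emp_cache),
                                       envir = .emp_cache)
    .emp_cache[[key]] <- prep
  }
  prep
}

emp_deviance <- function(cohort, model) {
  w <- cohort$workers
  if (!nrow(w)) return(0)
  prep <- emp_prep_cached(cohort)
  logfac <- emp_logfac(model, prep$workers)
  pieces <- emp_pieces(model, prep, logfac)
  if (is.null(pieces)) stopf("invalid parameterization: ERR factor <= 0")
  H <- as.vector(rowsum(pieces$piece, prep$w, reorder = TRUE))
  ll <- -H
  ev <- which(prep$event == 1)
  if (length(ev)) {
    fac <- 1 + model$err_lambda * prep$d_out[ev] *
      (prep$a_out[ev] < model$err_mu)
    if (any(fac <= 0)) stopf("invalid parameterization: ERR factor <= 0")
    h <- exp(emp_log_baseline(model, prep$a_out[ev], prep$year_out[ev]) +
               logfac[ev]) * fac
    ll[ev] <- ll[ev] + ifelse(h > 0, log(h), -Inf)
  }
  if (any(!is.finite(ll))) {
    out <- Inf
    attr(out, "bad_records") <- w$id[!is.finite(ll)]
    return(out)
  }
  -2 * sum(ll)
}

#' Likelihood-ratio test between nested fits
#'
#' Upper-tail \eqn{\chi^2_{df}} probability of the deviance difference.
#'
#' @param dev_null,dev_alt Deviances of the null and the nested alternative
#'   (\code{dev_alt <= dev_null} up to numerical tolerance).
#' @param df Degrees of freedom (number of extra parameters).
#' @return p-value.
#' @examples
#' lrt(10, 6.16, df = 1)  # ~0.05
#' @export
lrt <- function(dev_null, dev_alt, df) {
  check_number(df, "df", min = 1)
  delta <- dev_null - dev_alt
  if (delta < -1e-6)
    stopf("negative LRT statistic (%g): models not nested or fit failed",
          delta)
  stats::pchisq(max(delta, 0), df = df, lower.tail = FALSE)
}
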