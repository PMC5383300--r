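# Synthetic occupational cohort generator.
#
# Emulates the structure the likelihood consumes: male workers hired over a
# fixed calendar window, follow-up from first employment to stroke, death,
# emigration or an administrative cutoff, categorical covariates assigned
# at entry, and annual external gamma-dose histories during employment with
# a heavy-tailed between-worker distribution calibrated to a target median
# cumulative dose. Stroke ages are drawn from the generating model's own
# survival function (inverse-CDF by default; the stochastic simulator path
# is retained as a cross-check, keeping generator and solver falsifiable
# against each other). Censoring is drawn independently of the latent cell
# state (non-informative).

#' Design of a synthetic occupational cohort
#'
#' Distributional assumptions without a data source (entry ages, employment
#' durations, covariate prevalences, censoring rates) are package defaults
#' chosen to be plausible for a mid-20th-century male nuclear workforce;
#' they are assumptions, not facts about any real cohort.
#'
#' @param n_workers Number of workers.
#' @param truth Generating model: a \code{\link{mechanistic_model}},
#'   \code{\link{rate_set}} (promoted to a mechanistic model), or
#'   \code{\link{empirical_model}}.
#' @param seed Integer seed; regenerating with the same design and seed
#'   reproduces the cohort exactly.
#' @param hire_year_range Calendar years of first employment (uniform).
#' @param entry_age Mean/sd/truncation of the entry-age distribution
#'   (truncated normal, years).
#' @param covariate_prevalences Per covariate, category probabilities.
#' @param dose_model Annual-dose lognormal parameters: between-worker and
#'   between-year log-sd, employment-duration distribution (truncated
#'   normal, years), target median cumulative dose (Gy; the overall dose
#'   scale is solved numerically to hit it), and an early-era dose
#'   multiplier \code{exp(era_log_slope * years before era_end)} reflecting
#'   higher doses at early plant operation.
#' @param censoring Other-cause mortality (Gompertz level per year at age 0
#'   and log-slope per year), emigration rate (per year), administrative
#'   end (calendar year).
#' @return An object of class \code{cohort_design}.
#' @export
cohort_design <- function(n_workers, truth, seed,
                          hire_year_range = c(1948, 1972),
                          entry_age = list(mean = 25, sd = 7, min = 18,
                                           max = 60),
                          covariate_prevalences = list(
                            smoking = c(nonsmoker = 0.25,
                                        smoker_or_ex = 0.65,
                                        unknown = 0.10),
                            blood_pressure = c(normal = 0.72,
                                               hypertensive = 0.20,
                                               unknown = 0.08),
                            graduation = c(higher = 0.15, none = 0.75,
                                           unknown = 0.10)),
                          dose_model = list(worker_log_sd = 1.2,
                                            year_log_sd = 0.5,
                                            duration_mean = 18,
                                            duration_sd = 12,
                                            duration_min = 1,
                                            duration_max = 45,
                                            target_median_gy = 0.28,
                                            era_log_slope = 0.15,
                                            era_end = 1963),
                          censoring = list(gompertz_level = 1.6e-4,
                                           gompertz_slope = 0.09,
                                           emigration_rate = 0.02,
                                           admin_end_year = 2008)) {
  check_number(n_workers, "n_workers", min = 1)
  check_number(seed, "seed")
  if (inherits(truth, "rate_set")) truth <- mechanistic_model(truth)
  if (!inherits(truth, "mechanistic_model") &&
      !inherits(truth, "empirical_model"))
    stopf("'truth' must be a mechanistic_model, rate_set or empirical_model")
  for (cv in names(covariate_prevalences)) {
    p <- covariate_prevalences[[cv]]
    if (abs(sum(p) - 1) > 1e-8)
      stopf("prevalences for '%s' must sum to 1", cv)
  }
  structure(list(n_workers = as.integer(n_workers), truth = truth,
                 seed = seed, hire_year_range = hire_year_range,
                 entry_age = entry_age,
                 covariate_prevalences = covariate_prevalences,
                 dose_model = dose_model, censoring = censoring),
            class = "cohort_design")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Draw a stroke age from a survival grid by inverse transform
#'
#' Returns the age \code{a} with \eqn{S(a) = U} for uniform \code{U}
#' (log-linear interpolation between grid points), or NA where
#' \eqn{U < S(\max age)} (no event within the grid).
#'
#' @param grid A \code{survival_grid} with non-increasing \code{S}.
#' @param n Number of draws.
#' @param u Optional uniforms (overrides \code{n}), e.g. for conditioning
#'   on event-free survival to an entry age.
#' @return Ages in years, NA for no event.
#' @export
stroke_age_from_survival <- function(grid, n = 1, u = NULL) {
  S <- grid$S
  if (is.unsorted(rev(S))) stopf("survival grid is not non-increasing")
  if (is.null(u)) u <- stats::runif(n)
  lnS <- log(S)
  smin <- S[length(S)]
  out <- rep(NA_real_, length(u))
  ok <- u >= smin & u <= 1
  if (any(ok))
    out[ok] <- stats::approx(rev(lnS), rev(grid$age), xout = log(u[ok]),
                             ties = "ordered")$y
  out
}

# Gompertz mortality age conditional on survival to a_in.
rgompertz_cond <- function(n, level, slope, a_in) {
  H_in <- level / slope * (exp(slope * a_in) - 1)
  e <- stats::rexp(n)
  log(slope * (e + H_in) / level + 1) / slope
}

#' Generate a synthetic cohort with recorded truth
#'
#' Per worker: hire year, entry age, covariates and employment duration are
#' drawn; annual doses are drawn lognormally during employment (scaled so
#' the sample median cumulative dose hits the design target); the stroke
#' age is drawn from the generating model's survival function conditional
#' on being stroke-free at entry; censoring is the minimum of other-cause
#' death (Gompertz), emigration (exponential) and the administrative
#' cutoff. Follow-up starts at first employment; \code{event = 1} iff the
#' stroke precedes all censoring causes.
#'
#' Radiation does not feed back on stroke risk during generation unless the
#' truth model carries a dose response (mechanistic) or ERR term
#' (empirical); with a dose response, per-worker dose histories enter the
#' survival solve.
#'
#' @param design A \code{\link{cohort_design}}.
#' @param method \code{"analytic"} (inverse-CDF from the solver, default)
#'   or \code{"simulate"} (stroke ages from the stochastic simulator;
#'   slower, used for cross-checks). Simulation ignores truth dose
#'   responses.
#' @return A \code{generated_cohort}: list with \code{cohort} (a
#'   \code{\link{stroke_cohort}}) and \code{truth_manifest}.
#' @export
generate_cohort <- function(design, method = c("analytic", "simulate")) {
  stopifnot(inherits(design, "cohort_design"))
  method <- match.arg(method)
  set.seed(as.integer(derive_seed(design$seed, 0)))
  n <- design$n_workers
  dm <- design$dose_model
  cn <- design$censoring
  ea <- design$entry_age
  hire <- sample(seq(design$hire_year_range[1], design$hire_year_range[2]),
                 n, replace = TRUE)
  age_in <- rtruncnorm1(n, ea$mean, ea$sd, ea$min, ea$max)
  birth_year <- hire - floor(age_in)
  covs <- lapply(design$covariate_prevalences, function(p)
    sample(names(p), n, replace = TRUE, prob = p))
  duration <- round(rtruncnorm1(n, dm$duration_mean, dm$duration_sd,
                                dm$duration_min, dm$duration_max))
  duration <- pmin(duration, cn$admin_end_year - hire + 1)
  worker_mu <- stats::rnorm(n, 0, dm$worker_log_sd)
  widx <- rep(seq_len(n), duration)
  yrs <- hire[widx] + sequence(duration) - 1
  era <- exp(dm$era_log_slope * pmax(dm$era_end - yrs, 0))
  dgy <- exp(worker_mu[widx] +
               stats::rnorm(length(yrs), 0, dm$year_log_sd)) * era
  doses <- data.frame(id = sprintf("w%06d", widx), calendar_year = yrs,
                      dose_gy = dgy, stringsAsFactors = FALSE)
  cum <- as.vector(rowsum(dgy, widx))
  scale <- dm$target_median_gy / stats::median(cum)
  doses$dose_gy <- doses$dose_gy * scale
  # stroke ages from the truth model, conditional on no stroke by entry
  workers <- data.frame(id = sprintf("w%06d", seq_len(n)),
                        birth_year = birth_year, age_in = age_in,
                        age_out = NA_real_, event = 0L,
                        smoking = covs$smoking,
                        blood_pressure = covs$blood_pressure,
                        graduation = covs$graduation,
                        stringsAsFactors = FALSE)
  max_age <- 110
  pre <- stroke_cohort(workers = transform(workers, age_out = age_in + 1e-3),
                       doses = doses)
  histories <- dose_histories(pre)
  stroke_age <- draw_stroke_ages(design$truth, workers, histories,
                                 max_age, method)
  death <- rgompertz_cond(n, cn$gompertz_level, cn$gompertz_slope, age_in)
  emig <- age_in + stats::rexp(n, cn$emigration_rate)
  admin <- cn$admin_end_year + 1 - birth_year
  cens <- pmin(death, emig, admin, max_age)
  stroke <- ifelse(is.na(stroke_age), Inf, stroke_age)
  workers$event <- as.integer(stroke < cens)
  workers$age_out <- pmin(stroke, cens)
  workers$age_out <- pmax(workers$age_out, workers$age_in + 1e-6)
  cohort <- stroke_cohort(workers, doses)
  manifest <- list(
    generator = "atheromod::generate_cohort", version = 1L,
    seed = design$seed, method = method,
    n_workers = n, person_years = person_years(cohort),
    n_cases = n_cases(cohort),
    truth = serialize_truth(design$truth),
    design = design[c("hire_year_range", "entry_age",
                      "covariate_prevalences", "dose_model", "censoring")])
  structure(list(cohort = cohort, truth_manifest = manifest),
            class = "generated_cohort")
}

draw_stroke_ages <- function(truth, workers, histories, max_age, method) {
  n <- nrow(workers)
  u <- stats::runif(n)
  if (method == "simulate") {
    rates0 <- if (inherits(truth, "mechanistic_model")) truth$rates
    else stopf("simulate method requires a mechanistic truth")
    ev <- function(a) evaluate_rates(truth$rates, truth$age_laws,
                                     truth$modifiers, NULL,
                                     parameter_context(a))
    ages <- simulate_stroke_ages(ev, n = n, max_age = max_age,
                                 steps_per_year = 365,
                                 seed = NULL, t_lag = rates0$t_lag)
    # condition on no stroke before entry: resample those workers
    for (r in 1:20) {
      bad <- which(!is.na(ages) & ages <= workers$age_in)
      if (!length(bad)) break
      ages[bad] <- simulate_stroke_ages(ev, n = length(bad),
                                        max_age = max_age,
                                        steps_per_year = 365, seed = NULL,
                                        t_lag = rates0$t_lag)
    }
    return(ages)
  }
  grid_ages <- seq(0, max_age, by = 0.5)
  if (inherits(truth, "mechanistic_model")) {
    if (!is.null(truth$dose_resp)) grid_ages <- seq(0, max_age, by = 1)
    mod_covs <- unique(vapply(truth$modifiers, `[[`, "", "covariate"))
    use_dose <- !is.null(truth$dose_resp)
    key <- if (length(mod_covs))
      do.call(paste, c(lapply(mod_covs, function(cv) workers[[cv]]),
                       sep = "|"))
    else rep("", n)
    if (use_dose) key <- paste(key, workers$id, sep = "#")
    out <- rep(NA_real_, n)
    for (k in unique(key)) {
      idx <- which(key == k)
      i0 <- idx[1]
      covs <- as.list(workers[i0, names(covariate_levels)])
      history <- if (use_dose) histories[[workers$id[i0]]]
      tl <- stratum_timeline(truth, covs, history)
      grid <- stroke_hazard_survival(tl, grid_ages,
                                     hazard_method =
                                       if (is_homogeneous(tl)) "auto"
                                       else "augmented")
      S_in <- exp(grid_logS_at(grid, workers$age_in[idx]))
      out[idx] <- stroke_age_from_survival(grid, u = u[idx] * S_in)
    }
    out
  } else {
    # exact inverse-CDF sampling: within a segment the hazard is
    # exp(L1 + slope (a - x1)) * fac, so the crossing age of the target
    # cumulative hazard has a closed form
    prep <- emp_worker_prep(workers, histories, workers$age_in,
                            rep(max_age, n))
    logfac <- emp_logfac(truth, workers)
    pieces <- emp_pieces(truth, prep, logfac)
    if (is.null(pieces)) stopf("infeasible empirical truth (ERR factor)")
    target <- -log(u)
    out <- rep(NA_real_, n)
    csum <- stats::ave(pieces$piece, prep$w, FUN = cumsum)
    H_before <- csum - pieces$piece
    hit <- which(csum >= target[prep$w] & H_before < target[prep$w])
    need <- target[prep$w[hit]] - H_before[hit]
    sl <- pieces$slope[hit]
    rate0 <- exp(pieces$L1[hit]) * pieces$fac[hit]
    da <- ifelse(abs(sl) < 1e-12, need / rate0,
                 log1p(sl * need / rate0) / sl)
    out[prep$w[hit]] <- prep$x1[hit] + da
    out
  }
}

serialize_truth <- function(truth) {
  if (inherits(truth, "mechanistic_model")) {
    list(kind = "mechanistic", rates = unclass(truth$rates),
         age_laws = lapply(truth$age_laws, unclass),
         modifiers = lapply(truth$modifiers, function(m)
           list(parameter = m$parameter, covariate = m$covariate,
                multipliers = as.list(m$multipliers))),
         dose_resp = if (!is.null(truth$dose_resp))
           unclass(truth$dose_resp))
  } else {
    list(kind = "empirical", model = unclass(truth))
  }
}

deserialize_truth <- function(x) {
  if (x$kind == "mechanistic") {
    r <- x$rates
    mechanistic_model(
      rate_set(nu0N = r$nu0N, gamma = r$gamma, nu1 = r$nu1,
               alpha = r$alpha, nu2 = r$nu2, t_lag = r$t_lag),
      age_laws = lapply(x$age_laws, function(l)
        age_power_law(l$parameter, l$psi, l$a0, l$offset)),
      modifiers = lapply(x$modifiers, function(m)
        covariate_modifier(m$parameter, m$covariate,
                           unlist(m$multipliers))),
      dose_resp = if (length(x$dose_resp))
        dose_response(x$dose_resp$parameter, x$dose_resp$mode,
                      x$dose_resp$lambda))
  } else {
    m <- x$model
    empirical_model(m$intercept, unlist(m$age_slopes),
                    unlist(m$cal_slopes), unlist(m$age_knots),
                    unlist(m$cal_knots),
                    lapply(m$covariate_factors, unlist),
                    m$err_lambda, m$err_mu)
  }
}

#' Write a truth manifest to JSON
#' @param manifest The \code{truth_manifest} of a generated cohort.
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_truth_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and validate a truth manifest
#' @param path JSON file written by \code{\link{write_truth_manifest}}.
#' @return The manifest list; the generating truth model can be rebuilt
#'   with \code{truth_from_manifest}.
#' @export
read_truth_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (fld in c("seed", "truth", "n_workers"))
    if (is.null(m[[fld]]))
      stopf("manifest lacks required field '%s'", fld)
  m
}

#' Rebuild the generating truth model from a manifest
#' @param manifest A manifest from \code{\link{read_truth_manifest}}.
#' @return The generating \code{\link{mechanistic_model}} or
#'   \code{\link{empirical_model}}.
#' @export
truth_from_manifest <- function(manifest) deserialize_truth(manifest$truth)
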