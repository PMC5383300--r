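#' Biological rate set of the atherosclerosis model
#'
#' The mechanistic model is parameterized by five per-year rates and a lag
#' time: the monocyte-uptake product \eqn{N\nu_0} (uptake of monocytes into
#' the arterial wall, identifiable only as the product of monocyte number and
#' per-monocyte rate), the macrophage proliferation rate \eqn{\alpha}, the
#' effective proliferation rate \eqn{\gamma = \alpha - \beta - \nu_1} (the
#' deviation from homeostasis of the macrophage population, stored instead of
#' the death/emigration rate \eqn{\beta}), the foam-cell formation rate
#' \eqn{\nu_1}, the per-foam-cell vulnerable-plaque formation rate
#' \eqn{\nu_2}, and the fixed lag \code{t_lag} from first vulnerable plaque
#' to stroke.
#'
#' Defaults fix \eqn{\alpha = 12} and \eqn{\nu_2 = 10^{-7}} per year and
#' \code{t_lag = 10} years; these are non-identifiable from cohort data and
#' are conventionally held fixed while \eqn{N\nu_0}, \eqn{\gamma} and
#' \eqn{\nu_1} are fitted within bounded ranges (see
#' \code{\link{default_rate_bounds}}).
#'
#' @param nu0N Monocyte-uptake product, per year.
#' @param gamma Effective macrophage proliferation rate, per year.
#' @param nu1 Foam-cell formation rate, per year.
#' @param alpha Macrophage proliferation rate, per year.
#' @param nu2 Vulnerable-plaque formation rate per foam cell, per year.
#' @param t_lag Lag from first vulnerable plaque to stroke, years.
#' @return An object of class \code{rate_set}.
#' @examples
#' r <- rate_set(nu0N = 4.5, gamma = 0.12, nu1 = 1.3)
#' beta_from_rates(r)
#' @export
rate_set <- function(nu0N, gamma, nu1, alpha = 12, nu2 = 1e-7, t_lag = 10) {
  check_number(nu0N, "nu0N", min = 0)
  # gamma is an effective (net) rate and may be negative: a shrinking
  # macrophage population has beta + nu1 > alpha. Feasibility is beta >= 0.
  check_number(gamma, "gamma")
  check_number(nu1, "nu1", min = 0)
  check_number(alpha, "alpha", min = 0)
  check_number(nu2, "nu2", min = 0)
  check_number(t_lag, "t_lag", min = 0)
  r <- structure(list(nu0N = nu0N, alpha = alpha, gamma = gamma,
                      nu1 = nu1, nu2 = nu2, t_lag = t_lag),
                 class = "rate_set")
  beta_from_rates(r)  # validates feasibility
  r
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Biological rate set (per year):\n")
  cat(sprintf("  N*nu0 = %g  alpha = %g  gamma = %g  nu1 = %g  nu2 = %g\n",
              x$nu0N, x$alpha, x$gamma, x$nu1, x$nu2))
  cat(sprintf("  derived beta = %g   t_lag = %g years\n",
              beta_from_rates(x), x$t_lag))
  invisible(x)
}

#' Derived macrophage death/emigration rate
#'
#' The stored parameterization uses the effective proliferation rate
#' \eqn{\gamma}; the death/emigration rate is always derived as
#' \eqn{\beta = \alpha - \gamma - \nu_1} and must be non-negative.
#' Combinations with \eqn{\gamma + \nu_1 > \alpha} are rejected: a negative
#' death rate is biologically meaningless, and the fitting machinery treats
#' such points as having infinite deviance.
#'
#' @param rates A \code{\link{rate_set}} or list with \code{alpha},
#'   \code{gamma}, \code{nu1}.
#' @return The rate \eqn{\beta} (per year).
#' @export
beta_from_rates <- function(rates) {
  beta <- rates$alpha - rates$gamma - rates$nu1
  if (beta < 0)
    stopf(paste0("infeasible parameterization: beta = alpha - gamma - nu1 = ",
                 "%g < 0 (alpha=%g, gamma=%g, nu1=%g)"),
          beta, rates$alpha, rates$gamma, rates$nu1)
  beta
}

#' Default fitting bounds for the free biological parameters
#'
#' Plausible ranges from order-of-magnitude biology: the monocyte influx must
#' account for the lesions seen in children (\eqn{N\nu_0 \in [1, 10]}), the
#' effective proliferation rate is bounded by lesion growth from about
#' \eqn{10^2} to \eqn{10^7} cells over 50 years
#' (\eqn{\gamma \in [0.1, 0.3]}), and \eqn{\nu_1 \in [0.1, 12]} with
#' \eqn{\nu_1 < \alpha}. Note the box admits corners with
#' \eqn{\gamma + \nu_1 > \alpha}, which are infeasible and rejected at
#' evaluation time.
#'
#' @return data.frame with columns name, lower, upper, start.
#' @export
default_rate_bounds <- function() {
  data.frame(name  = c("nu0N", "gamma", "nu1"),
             lower = c(1, 0.1, 0.1),
             upper = c(10, 0.3, 12),
             start = c(4, 0.2, 1),
             stringsAsFactors = FALSE)
}

#' Power-law age dependence of a biological parameter
#'
#' A rate \eqn{\eta} may depend on age as
#' \deqn{\eta(a) = \eta(a_0) \left(\frac{a + 10}{a_0 + 10}\right)^{\psi}}
#' with reference age \eqn{a_0} fixed per parameter (10 years for
#' \eqn{N\nu_0}, 40 years for \eqn{\alpha}, \eqn{\gamma}, \eqn{\nu_1},
#' 60 years for \eqn{\nu_2}) and exponent \eqn{\psi \in [-1, 1]}. The
#' 10-year offset regularizes the law at very young ages.
#'
#' @param parameter One of \code{"nu0N"}, \code{"alpha"}, \code{"gamma"},
#'   \code{"nu1"}, \code{"nu2"}.
#' @param psi Dimensionless exponent in \code{[-1, 1]}.
#' @param a0 Reference age in years; defaults to the conventional value for
#'   the parameter.
#' @param offset Regularization constant in years (fixed at 10).
#' @return An object of class \code{age_power_law}.
#' @export
age_power_law <- function(parameter, psi, a0 = NULL, offset = 10) {
  parameter <- match.arg(parameter, c("nu0N", "alpha", "gamma", "nu1", "nu2"))
  check_number(psi, "psi", min = -1, max = 1)
  if (is.null(a0))
    a0 <- c(nu0N = 10, alpha = 40, gamma = 40, nu1 = 40, nu2 = 60)[[parameter]]
  check_number(a0, "a0", min = 0)
  structure(list(parameter = parameter, psi = psi, a0 = a0, offset = offset),
            class = "age_power_law")
}

#' Evaluate a power-law age dependence
#'
#' @param value_at_a0 Rate at the reference age (per year).
#' @param law An \code{\link{age_power_law}}.
#' @param age Age in years (vectorized).
#' @return The rate at \code{age}.
#' @examples
#' age_scaled(2.4, age_power_law("nu0N", psi = 1), age = 50)  # 7.2
#' @export
age_scaled <- function(value_at_a0, law, age) {
  stopifnot(inherits(law, "age_power_law"), all(age >= 0))
  value_at_a0 * ((age + law$offset) / (law$a0 + law$offset))^law$psi
}

#' Categorical covariate modifier of a biological parameter
#'
#' Multiplies a rate by a category-specific positive factor, with the
#' reference category fixed at 1. Used, for example, to let hypertension act
#' on the plaque formation rate \eqn{\nu_2}.
#'
#' @param parameter Target rate name.
#' @param covariate Covariate name (e.g. \code{"blood_pressure"}).
#' @param multipliers Named numeric vector of positive factors, one per
#'   category; the reference category must have factor 1.
#' @param reference Reference category name; defaults to the first entry of
#'   \code{multipliers}.
#' @return An object of class \code{covariate_modifier}.
#' @export
covariate_modifier <- function(parameter, covariate, multipliers,
                               reference = names(multipliers)[1]) {
  parameter <- match.arg(parameter, c("nu0N", "alpha", "gamma", "nu1", "nu2"))
  if (is.null(names(multipliers)) || any(names(multipliers) == ""))
    stopf("'multipliers' must be a fully named numeric vector")
  if (any(multipliers <= 0)) stopf("all multipliers must be > 0")
  if (!reference %in% names(multipliers))
    stopf("reference category '%s' not among multipliers", reference)
  if (abs(multipliers[[reference]] - 1) > 1e-12)
    stopf("reference category '%s' must have multiplier 1", reference)
  structure(list(parameter = parameter, covariate = covariate,
                 multipliers = multipliers, reference = reference),
            class = "covariate_modifier")
}

#' Linear dose response of a biological parameter
#'
#' Radiation modifies a rate as \eqn{\eta(d) = \eta(0)(1 + \lambda d)}
#' (persistent effect of hitherto accumulated dose \eqn{d}, Gy) or
#' \eqn{\eta(r) = \eta(0)(1 + \lambda r)} (short-term effect of the
#' annual dose rate \eqn{r}, Gy/year). The realized factor
#' \eqn{1 + \lambda x} must remain positive over the data's dose range;
#' non-positive factors are an error (the optimizer treats them as infinite
#' deviance, never clamps).
#'
#' @param parameter Target rate name.
#' @param mode \code{"cumulative_dose"} or \code{"annual_dose_rate"}.
#' @param lambda Slope, per Gy (cumulative mode) or per Gy/year (rate mode).
#' @return An object of class \code{dose_response}.
#' @export
dose_response <- function(parameter,
                          mode = c("cumulative_dose", "annual_dose_rate"),
                          lambda) {
  parameter <- match.arg(parameter, c("nu0N", "alpha", "gamma", "nu1", "nu2"))
  mode <- match.arg(mode)
  check_number(lambda, "lambda")
  structure(list(parameter = parameter, mode = mode, lambda = lambda),
            class = "dose_response")
}

#' Apply a dose response to a base rate
#'
#' @param base Base rate (per year), at zero dose.
#' @param dr A \code{\link{dose_response}}.
#' @param context A \code{\link{parameter_context}} supplying the cumulative
#'   dose and annual dose rate.
#' @return The modified rate.
#' @export
dose_modified <- function(base, dr, context) {
  stopifnot(inherits(dr, "dose_response"))
  x <- switch(dr$mode,
              cumulative_dose = context$cumulative_dose,
              annual_dose_rate = context$annual_dose_rate)
  fac <- 1 + dr$lambda * x
  if (any(fac <= 0))
    stopf("invalid parameterization: dose factor 1 + lambda*x = %g <= 0",
          min(fac))
  base * fac
}

#' Evaluation context for realized rates
#'
#' Bundles the age, covariate categories, radiation exposure and calendar
#' year at which rates are evaluated. The cumulative dose \code{d} is the
#' annual dose rate integrated up to the age considered.
#'
#' @param age Age in years.
#' @param covariates Named character vector/list, covariate -> category.
#' @param cumulative_dose Cumulative external gamma dose, Gy.
#' @param annual_dose_rate Annual dose rate, Gy per year.
#' @param calendar_year Calendar year (integer), optional.
#' @return An object of class \code{parameter_context}.
#' @export
parameter_context <- function(age, covariates = list(), cumulative_dose = 0,
                              annual_dose_rate = 0, calendar_year = NA) {
  check_number(age, "age", min = 0)
  check_number(cumulative_dose, "cumulative_dose", min = 0)
  check_number(annual_dose_rate, "annual_dose_rate", min = 0)
  structure(list(age = age, covariates = as.list(covariates),
                 cumulative_dose = cumulative_dose,
                 annual_dose_rate = annual_dose_rate,
                 calendar_year = calendar_year),
            class = "parameter_context")
}

#' Realized rate set under age laws, covariate modifiers and dose response
#'
#' Transforms each rate of a base \code{\link{rate_set}} in fixed order:
#' age power law, then categorical multipliers, then the dose factor.
#' The derived death rate \eqn{\beta} is recomputed from the transformed
#' \eqn{\alpha}, \eqn{\gamma}, \eqn{\nu_1} and validated non-negative after
#' the composition (an age law on \eqn{\alpha} alone may render the point
#' infeasible).
#'
#' @param base A \code{\link{rate_set}}.
#' @param laws List of \code{\link{age_power_law}}s (at most one per
#'   parameter).
#' @param modifiers List of \code{\link{covariate_modifier}}s.
#' @param dr A single \code{\link{dose_response}} or NULL.
#' @param context A \code{\link{parameter_context}}.
#' @return A \code{\link{rate_set}} of realized rates.
#' @export
evaluate_rates <- function(base, laws = list(), modifiers = list(),
                           dr = NULL, context = parameter_context(age = 0)) {
  stopifnot(inherits(base, "rate_set"))
  if (inherits(laws, "age_power_law")) laws <- list(laws)
  if (inherits(modifiers, "covariate_modifier")) modifiers <- list(modifiers)
  if (length(laws) &&
      anyDuplicated(vapply(laws, `[[`, "", "parameter")))
    stopf("at most one age power law per parameter")
  vals <- unclass(base)[c("nu0N", "alpha", "gamma", "nu1", "nu2")]
  for (law in laws)
    vals[[law$parameter]] <- age_scaled(vals[[law$parameter]], law,
                                        context$age)
  for (mod in modifiers) {
    cat_ <- context$covariates[[mod$covariate]]
    if (is.null(cat_))
      stopf("context lacks covariate '%s' needed by a modifier",
            mod$covariate)
    if (!cat_ %in% names(mod$multipliers))
      stopf("category '%s' not defined for modifier on %s", cat_,
            mod$parameter)
    vals[[mod$parameter]] <- vals[[mod$parameter]] *
      mod$multipliers[[cat_]]
  }
  if (!is.null(dr))
    vals[[dr$parameter]] <- dose_modified(vals[[dr$parameter]], dr, context)
  rate_set(nu0N = vals$nu0N, gamma = vals$gamma, nu1 = vals$nu1,
           alpha = vals$alpha, nu2 = vals$nu2, t_lag = base$t_lag)
}

#' Upper bound on the effective proliferation rate
#'
#' If a lesion grows by effective exponential proliferation from about
#' \code{n_seed} macrophages (the most that monocyte influx alone can
#' supply) to at most \code{n_max} foam cells and debris over
#' \code{duration} years, with foam-cell-to-macrophage ratio
#' \code{ratio_nu1_gamma} \eqn{= \nu_1/\gamma}, then
#' \deqn{\gamma \lesssim \frac{\ln(n_{max}/n_{seed}) - \ln(\nu_1/\gamma)}
#'   {duration}.}
#' With \eqn{n_{max} = 10^7}, \eqn{n_{seed} = 10^2}, ratio 3 and 50 years
#' this gives about 0.2 per year; the logarithms make the bound insensitive
#' to the inputs.
#'
#' @param n_max Maximal foam-cell count of a sizable plaque.
#' @param n_seed Macrophage count at which proliferation takes over.
#' @param ratio_nu1_gamma Foam-cell-to-macrophage number ratio.
#' @param duration Growth period, years.
#' @return Bound on \eqn{\gamma}, per year.
#' @examples
#' proliferation_bound(1e7, 1e2, 3, 50)  # ~0.21, i.e. 0.2 to one decimal
#' @export
proliferation_bound <- function(n_max, n_seed, ratio_nu1_gamma, duration) {
  check_number(n_max, "n_max", min = .Machine$double.xmin)
  check_number(n_seed, "n_seed", min = .Machine$double.xmin)
  check_number(ratio_nu1_gamma, "ratio_nu1_gamma",
               min = .Machine$double.xmin)
  check_number(duration, "duration", min = .Machine$double.xmin)
  if (n_max <= n_seed) stopf("'n_max' must exceed 'n_seed'")
  (log(n_max / n_seed) - log(ratio_nu1_gamma)) / duration
}

#' Attributable fraction under a linear excess relative risk
#'
#' For a hazard multiplied by \eqn{1 + ERR \cdot d}, the fraction of cases
#' attributable to the exposure is \eqn{ERR \cdot d / (1 + ERR \cdot d)}.
#'
#' @param err_per_gy Excess relative risk per Gy.
#' @param dose Cumulative dose, Gy.
#' @return Fraction in \eqn{[0, 1)} for non-negative arguments.
#' @examples
#' attributable_fraction(0.1, 2)  # 1/6: under 20% even at 2 Gy
#' @export
attributable_fraction <- function(err_per_gy, dose) {
  check_number(err_per_gy, "err_per_gy")
  check_number(dose, "dose", min = 0)
  x <- err_per_gy * dose
  if (1 + x <= 0) stopf("excess relative risk term 1 + ERR*d = %g <= 0",
                        1 + x)
  x / (1 + x)
}
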