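# Exact Monte-Carlo simulation of the (M, F, R) cell-count process.
#
# Transitions within a step of length dt are drawn as independent Poisson
# counts computed from the state at step start (parallel update):
#   influx      ~ Pois(N nu0 dt)      new macrophages from monocyte uptake
#   births      ~ Pois(alpha M dt)    macrophage proliferation
#   deaths      ~ Pois(beta M dt)     apoptosis / emigration
#   conversions ~ Pois(nu1 M dt)      macrophage -> foam cell
#   plaques     ~ Pois(nu2 F dt)      foam cell -> vulnerable plaque
# M and F are floored at zero after applying the decrements; with the
# default 365 steps per year and realistic rates, flooring is rare.
# Aggregate draws are equivalent in distribution to per-cell simulation in
# the dt -> 0 limit and cost O(1) per step.

#' One Poisson update step of the cell-count process
#'
#' @param state List with \code{age}, \code{M}, \code{F}, \code{R}.
#' @param rates A \code{\link{rate_set}}.
#' @param dt Step length, years.
#' @return Updated state list.
#' @export
lesion_step <- function(state, rates, dt) {
  check_number(dt, "dt", min = .Machine$double.xmin)
  beta <- rates$alpha - rates$gamma - rates$nu1
  influx <- stats::rpois(1, rates$nu0N * dt)
  births <- stats::rpois(1, rates$alpha * state$M * dt)
  deaths <- stats::rpois(1, beta * state$M * dt)
  conv   <- stats::rpois(1, rates$nu1 * state$M * dt)
  plaq   <- stats::rpois(1, rates$nu2 * state$F * dt)
  list(age = state$age + dt,
       M = max(state$M + influx + births - deaths - conv, 0),
       F = max(state$F + conv - plaq, 0),
       R = state$R + plaq)
}

# Vectorized batch simulation across replicates (single seeded stream).
# rate_evaluator: function(age) -> rate_set, re-evaluated once per year.
# Returns annual snapshot matrices and first-plaque ages (step resolution).
simulate_batch <- function(rate_evaluator, n_replicates, max_age,
                           steps_per_year = 365, seed = NULL,
                           track_counts = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_replicates
  dt <- 1 / steps_per_year
  M <- numeric(n); F_ <- numeric(n); R <- numeric(n)
  first_plaque <- rep(NA_real_, n)
  n_years <- ceiling(max_age)
  MF <- if (track_counts)
    matrix(0, nrow = n_years + 1L, ncol = n) else NULL
  for (year in seq_len(n_years) - 1L) {
    r <- rate_evaluator(year + 0.5)
    beta <- r$alpha - r$gamma - r$nu1
    mu_in <- r$nu0N * dt
    for (step in seq_len(steps_per_year)) {
      influx <- stats::rpois(n, mu_in)
      births <- stats::rpois(n, r$alpha * M * dt)
      deaths <- stats::rpois(n, beta * M * dt)
      conv   <- stats::rpois(n, r$nu1 * M * dt)
      plaq   <- stats::rpois(n, r$nu2 * F_ * dt)
      M <- pmax(M + influx + births - deaths - conv, 0)
      F_ <- pmax(F_ + conv - plaq, 0)
      new_plaque <- plaq > 0 & is.na(first_plaque)
      if (any(new_plaque))
        first_plaque[new_plaque] <- year + step * dt
      R <- R + plaq
    }
    if (track_counts) MF[year + 2L, ] <- M + F_
  }
  list(MF = MF, M = M, F = F_, R = R, first_plaque = first_plaque,
       ages = 0:n_years)
}

#' Simulate one individual's lesion trajectory
#'
#' Starts from the absence of any atherosclerotic lesion at birth
#' (\code{M = F = R = 0} at age 0) and updates the cell counts
#' \code{steps_per_year} times per simulated year, with rates re-evaluated
#' once per year. Returns annual snapshots and the first step-age at which
#' a vulnerable plaque exists.
#'
#' @param rate_evaluator Function age -> \code{\link{rate_set}}, or a
#'   \code{\link{rate_set}} for constant rates.
#' @param max_age Simulation horizon, years.
#' @param steps_per_year Sub-annual update count (default 365).
#' @param seed Optional integer seed.
#' @return List with \code{trajectory} (data.frame age, M_plus_F) and
#'   \code{first_plaque_age} (NA if no plaque by \code{max_age}).
#' @export
simulate_individual <- function(rate_evaluator, max_age = 100,
                                steps_per_year = 365, seed = NULL) {
  rate_evaluator <- as_rate_evaluator(rate_evaluator)
  sim <- simulate_batch(rate_evaluator, 1L, max_age, steps_per_year, seed)
  list(trajectory = data.frame(age = sim$ages, M_plus_F = sim$MF[, 1]),
       first_plaque_age = sim$first_plaque[1])
}

as_rate_evaluator <- function(x) {
  if (inherits(x, "rate_set")) function(age) x
  else if (inherits(x, "parameter_timeline"))
    function(age) timeline_rates_at(x, age)
  else if (is.function(x)) x
  else stopf("'rate_evaluator' must be a function, rate_set or timeline")
}

#' Age-dependent prevalence of simulated lesions
#'
#' Runs replicate simulations and reports, for each annual age and each
#' threshold \code{X}, the fraction of replicates whose current macrophage
#' plus foam-cell count is at least \code{X} (lesions may regress, so the
#' current count, not the running maximum, is used).
#'
#' @inheritParams simulate_individual
#' @param thresholds Ascending cell-count thresholds (default
#'   \code{c(1e2, 1e3, 1e4)}, minimal through sizable lesions).
#' @param n_replicates Number of replicates (default 500).
#' @param seed Integer seed for the replicate batch.
#' @return A \code{prevalence_curve} data.frame with columns \code{age},
#'   \code{threshold}, \code{fraction}.
#' @export
lesion_prevalence <- function(rate_evaluator, max_age = 100,
                              thresholds = c(1e2, 1e3, 1e4),
                              n_replicates = 500, steps_per_year = 365,
                              seed = 1) {
  if (is.unsorted(thresholds))
    stopf("'thresholds' must be sorted ascending")
  rate_evaluator <- as_rate_evaluator(rate_evaluator)
  sim <- simulate_batch(rate_evaluator, n_replicates, max_age,
                        steps_per_year, seed)
  out <- do.call(rbind, lapply(thresholds, function(th)
    data.frame(age = sim$ages, threshold = th,
               fraction = rowMeans(sim$MF >= th))))
  class(out) <- c("prevalence_curve", "data.frame")
  out
}

#' Simulate stroke ages from the cell-count process
#'
#' Stroke occurs exactly \code{t_lag} years after creation of the first
#' vulnerable plaque. Returns one stroke age per replicate, NA where no
#' plaque formed by \code{max_age - t_lag}.
#'
#' @inheritParams lesion_prevalence
#' @param t_lag Lag from first plaque to stroke, years; defaults to the
#'   evaluator's value at age 0.
#' @param n Number of replicates.
#' @return Numeric vector of stroke ages (years) with NAs.
#' @export
simulate_stroke_ages <- function(rate_evaluator, n = 500, max_age = 100,
                                 steps_per_year = 365, seed = 1,
                                 t_lag = NULL) {
  rate_evaluator <- as_rate_evaluator(rate_evaluator)
  if (is.null(t_lag)) t_lag <- rate_evaluator(0)$t_lag
  sim <- simulate_batch(rate_evaluator, n, max_age - t_lag, steps_per_year,
                        seed, track_counts = FALSE)
  sim$first_plaque + t_lag
}
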