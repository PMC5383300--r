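# Analytic survival/hazard solver.
#
# Because monocytes, macrophages and foam cells evolve independently, the
# infinite master equation of the cell-count process reduces to
# low-dimensional backward Kolmogorov ODEs:
#
#   v(s,t) = P(one foam cell at age s seeds no vulnerable plaque by t)
#          = exp(-int_s^t nu2(x) dx)
#   u(s,t) = P(one macrophage at age s yields no plaque by t), solving the
#            backward Riccati equation
#            du/ds = (alpha+beta+nu1) u - alpha u^2 - beta - nu1 v(s,t),
#            u(t,t) = 1,  beta = alpha - gamma - nu1.
#
# Poisson immigration of monocytes at rate N*nu0(s) then gives the survival
# of the first vulnerable plaque,
#   S_R(t) = exp(-int_0^t N nu0(s) (1 - u(s,t)) ds),
# and stroke survival is the lag-shifted S(a) = S_R(a - t_lag).
#
# For a time-homogeneous timeline u(s,t) = U(t-s), and a single forward
# solve yields both S_R and the exact hazard h_R(t) = N nu0 (1 - U(t)).

ODE_RTOL <- 1e-8
ODE_ATOL <- 1e-10

# Cumulative integral of a piecewise-constant rate from 0 to x (vectorized).
pc_cumint <- function(breaks, values, max_age, x) {
  knots <- c(breaks, max_age)
  cum <- c(0, cumsum(values * diff(knots)))
  i <- pmin(findInterval(x, knots, rightmost.closed = TRUE), length(values))
  cum[i] + values[i] * (x - knots[i])
}

#' Probability that a foam cell seeds no vulnerable plaque
#'
#' \eqn{v(s,t) = \exp(-\int_s^t \nu_2(x)\,dx)}: the probability that a
#' single foam cell present at age \code{s} has produced no vulnerable
#' plaque by age \code{t}. Exact for piecewise-constant \eqn{\nu_2};
#' multiplicative over adjacent intervals.
#'
#' @param timeline A \code{\link{parameter_timeline}}.
#' @param s,t Ages in years, \code{0 <= s <= t} (\code{s} may be a vector).
#' @return Probabilities in \code{(0, 1]}.
#' @export
foam_cell_safe_prob <- function(timeline, s, t) {
  stopifnot(inherits(timeline, "parameter_timeline"))
  check_number(t, "t", min = 0)
  if (any(s < 0) || any(s > t)) stopf("need 0 <= s <= t")
  nu2 <- timeline_rate_vector(timeline, "nu2")
  exp(-(pc_cumint(timeline$breakpoints, nu2, timeline$max_age, t) -
          pc_cumint(timeline$breakpoints, nu2, timeline$max_age, s)))
}

# Backward sweep for one horizon t: integrates (u, v[, p]) from s = t down
# to s = 0 interval by interval, returning per-interval node ages and u
# (and p) values, plus the accumulated immigration integrals.
backward_sweep <- function(timeline, t, node_step = 0.25,
                           augmented = FALSE) {
  breaks <- timeline$breakpoints
  nu2_t <- timeline_rates_at(timeline, min(t, timeline$max_age - 1e-9))$nu2
  state <- c(u = 1, v = 1, if (augmented) c(p = 0))
  int_S <- 0      # int nu0N (1 - u) ds
  int_h <- 0      # int nu0N (-p) ds
  k <- timeline_interval(timeline, min(t, timeline$max_age - 1e-9))
  hi <- t
  while (hi > 0) {
    lo <- if (k >= 1) breaks[k] else 0
    r <- timeline$rates[[k]]
    beta <- r$alpha - r$gamma - r$nu1
    deriv <- function(s, y, parms) {
      du <- (r$alpha + beta + r$nu1) * y[1] - r$alpha * y[1]^2 - beta -
        r$nu1 * y[2]
      dv <- r$nu2 * y[2]
      if (augmented) {
        dp <- (r$alpha + beta + r$nu1 - 2 * r$alpha * y[1]) * y[3] +
          r$nu1 * nu2_t * y[2]
        list(c(du, dv, dp))
      } else list(c(du, dv))
    }
    n_nodes <- max(2L, ceiling((hi - lo) / node_step) + 1L)
    times <- seq(hi, lo, length.out = n_nodes)
    sol <- deSolve::ode(y = state, times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = ODE_RTOL, atol = ODE_ATOL)
    u_nodes <- rev(sol[, "u"])
    s_nodes <- rev(sol[, "time"])
    int_S <- int_S + r$nu0N * trapz(s_nodes, 1 - u_nodes)
    if (augmented)
      int_h <- int_h + r$nu0N * trapz(s_nodes, -rev(sol[, "p"]))
    state <- sol[nrow(sol), -1]
    hi <- lo
    k <- k - 1L
  }
  list(S = exp(-int_S), h = int_h, u0 = unname(state["u"]))
}

#' Probability that a macrophage lineage produces no vulnerable plaque
#'
#' \eqn{u(s,t)}: the probability that a single macrophage present at age
#' \code{s}, together with all its descendants (daughter macrophages and
#' foam cells), produces no vulnerable plaque by age \code{t}. Solves the
#' backward branching-process equation
#' \deqn{\partial u/\partial s = (\alpha+\beta+\nu_1)u - \alpha u^2 - \beta
#'   - \nu_1 v(s,t), \quad u(t,t) = 1}
#' with \eqn{\beta = \alpha - \gamma - \nu_1}, backward from \code{t} with
#' an adaptive solver (relative tolerance 1e-8).
#'
#' @inheritParams foam_cell_safe_prob
#' @return Probabilities in \code{(0, 1]}, one per element of \code{s}.
#' @export
macrophage_safe_prob <- function(timeline, s, t) {
  stopifnot(inherits(timeline, "parameter_timeline"))
  check_number(t, "t", min = 0)
  if (any(s < 0) || any(s > t)) stopf("need 0 <= s <= t")
  if (t == 0) return(rep(1, length(s)))
  breaks <- timeline$breakpoints
  out <- numeric(length(s))
  # integrate once from t to min(s), reading off u at the requested ages
  state <- c(u = 1, v = 1)
  hi <- t
  k <- timeline_interval(timeline, min(t, timeline$max_age - 1e-9))
  s_nodes <- t
  u_nodes <- 1
  while (hi > min(s)) {
    lo <- max(if (k >= 1) breaks[k] else 0, min(s))
    r <- timeline$rates[[k]]
    beta <- r$alpha - r$gamma - r$nu1
    deriv <- function(ss, y, parms)
      list(c((r$alpha + beta + r$nu1) * y[1] - r$alpha * y[1]^2 - beta -
               r$nu1 * y[2],
             r$nu2 * y[2]))
    here <- s[s >= lo - 1e-12 & s < hi - 1e-12]
    times <- sort(unique(pmin(pmax(c(hi, lo, here), lo), hi)),
                  decreasing = TRUE)
    if (length(times) == 1L) break
    sol <- deSolve::ode(y = state, times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = ODE_RTOL, atol = ODE_ATOL)
    s_nodes <- c(s_nodes, sol[-1, "time"])
    u_nodes <- c(u_nodes, sol[-1, "u"])
    state <- sol[nrow(sol), -1]
    hi <- lo
    k <- k - 1L
    if (hi <= 0) break
  }
  out <- u_nodes[vapply(s, function(si) which.min(abs(s_nodes - si)), 1L)]
  pmin(pmax(out, 0), 1)
}

# Fast path: time-homogeneous timeline, u(s,t) = U(t-s). One forward
# solve of
#   dU/dtau = beta + nu1 exp(-nu2 tau) + alpha U^2 - (alpha+beta+nu1) U
# augmented with the exponent integral I(tau) = int_0^tau (1 - U), so that
# S_R = exp(-nu0N I) and h_R = nu0N (1 - U) exactly (to ODE tolerance),
# with solver output only at the requested ages.
solve_homogeneous <- function(rates, taus, fine_step = 0.05) {
  tmax <- max(taus)
  if (tmax == 0)
    return(list(tau = taus, S = rep(1, length(taus)),
                h = rep(0, length(taus))))
  beta <- rates$alpha - rates$gamma - rates$nu1
  grid <- sort(unique(c(0, taus)))
  deriv <- function(tau, y, parms)
    list(c(beta + rates$nu1 * exp(-rates$nu2 * tau) +
             rates$alpha * y[1]^2 -
             (rates$alpha + beta + rates$nu1) * y[1],
           1 - y[1]))
  sol <- deSolve::ode(y = c(U = 1, I = 0), times = grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = ODE_RTOL, atol = ODE_ATOL)
  U <- pmin(pmax(sol[, "U"], 0), 1)
  I <- pmax(sol[, "I"], 0)
  idx <- match(taus, grid)
  list(tau = taus, S = exp(-rates$nu0N * I[idx]),
       h = (rates$nu0N * (1 - U))[idx])
}

# Core: S_R and h_R of the first vulnerable plaque at requested plaque-time
# ages, choosing the fast homogeneous path when possible.
solve_plaque_process <- function(timeline, taus, fine_step = 0.05,
                                 hazard_method = c("auto", "fd",
                                                   "augmented")) {
  hazard_method <- match.arg(hazard_method)
  taus <- as.double(taus)
  if (any(taus < 0)) stopf("plaque-time ages must be >= 0")
  if (any(taus > timeline$max_age + 1e-9))
    stopf("requested age %g exceeds timeline coverage %g", max(taus),
          timeline$max_age)
  if (is_homogeneous(timeline) && hazard_method != "fd")
    return(solve_homogeneous(timeline$rates[[1]], taus, fine_step))
  S <- numeric(length(taus))
  h <- numeric(length(taus))
  delta <- 0.05
  for (i in seq_along(taus)) {
    t0 <- taus[i]
    if (t0 == 0) { S[i] <- 1; h[i] <- 0; next }
    if (hazard_method == "augmented") {
      sw <- backward_sweep(timeline, t0, augmented = TRUE)
      S[i] <- sw$S
      h[i] <- sw$h
    } else {
      S[i] <- backward_sweep(timeline, t0)$S
      lo <- max(t0 - delta, 0)
      hi <- min(t0 + delta, timeline$max_age)
      s_lo <- if (lo == 0) 1 else backward_sweep(timeline, lo)$S
      s_hi <- backward_sweep(timeline, hi)$S
      h[i] <- (log(s_lo) - log(s_hi)) / (hi - lo)
    }
  }
  list(tau = taus, S = S, h = pmax(h, 0))
}

#' Survival of the first vulnerable plaque
#'
#' \eqn{S_R(t) = \exp(-\int_0^t N\nu_0(s)(1 - u(s,t))\,ds)}: the
#' probability that no vulnerable plaque has formed by age \code{t}, from
#' Poisson immigration of monocyte lineages.
#'
#' @param timeline A \code{\link{parameter_timeline}}.
#' @param t Ages in years (vectorized).
#' @return Probabilities in \code{(0, 1]}, non-increasing in \code{t}.
#' @export
survival_no_plaque <- function(timeline, t) {
  stopifnot(inherits(timeline, "parameter_timeline"))
  solve_plaque_process(timeline, t, hazard_method = "auto")$S
}

new_survival_grid <- function(ages, S, h, t_lag) {
  structure(data.frame(age = ages, S = S, h = h),
            t_lag = t_lag, class = c("survival_grid", "data.frame"))
}

#' Stroke-free survival and hazard implied by the mechanistic model
#'
#' Stroke occurs exactly \code{t_lag} years after the first vulnerable
#' plaque, so \eqn{S(a) = S_R(\max(a - t_{lag}, 0))} and the stroke hazard
#' is the first-plaque hazard evaluated at \eqn{a - t_{lag}} (zero for
#' \eqn{a \le t_{lag}}). For a time-homogeneous timeline the hazard is the
#' exact derivative \eqn{h_R(t) = N\nu_0 (1 - U(t))}; otherwise it is
#' obtained by central finite differences of \eqn{-\ln S_R} with step
#' 0.05 years (\code{hazard_method = "fd"}, the default for
#' age-inhomogeneous timelines) or from an augmented backward ODE for the
#' exact \eqn{t}-derivative (\code{"augmented"}, used for validation).
#'
#' @param timeline A \code{\link{parameter_timeline}}.
#' @param ages Age grid, years.
#' @param hazard_method \code{"auto"}, \code{"fd"} or \code{"augmented"}.
#' @param fine_step Internal integration output step, years.
#' @return A \code{survival_grid} data frame with columns \code{age},
#'   \code{S}, \code{h}.
#' @export
stroke_hazard_survival <- function(timeline, ages,
                                   hazard_method = c("auto", "fd",
                                                     "augmented"),
                                   fine_step = 0.05) {
  stopifnot(inherits(timeline, "parameter_timeline"))
  hazard_method <- match.arg(hazard_method)
  ages <- as.double(ages)
  taus <- pmax(ages - timeline$t_lag, 0)
  sol <- solve_plaque_process(timeline, taus, fine_step, hazard_method)
  new_survival_grid(ages, sol$S, sol$h, timeline$t_lag)
}

#' Age-dependent relative risk between two parameter profiles
#'
#' Hazard ratio \eqn{h_a(age)/h_b(age)} on a grid. In the mechanistic model
#' a multiplicative change of \eqn{\nu_2} yields a ratio close to the
#' multiplier just above \code{t_lag} that then declines with age: exposed
#' subjects with advanced lesions leave the risk set earlier, depleting the
#' high-burden stratum (a selection effect). A multiplicative factor on the
#' hazard itself (the empirical convention) would give a constant ratio.
#'
#' @param timeline_a,timeline_b Timelines sharing \code{t_lag}.
#' @param ages Age grid, years; hazards of \code{timeline_b} must be
#'   positive there.
#' @return data.frame with columns \code{age}, \code{rr}.
#' @export
relative_risk <- function(timeline_a, timeline_b, ages) {
  if (timeline_a$t_lag != timeline_b$t_lag)
    stopf("timelines must share t_lag")
  ha <- stroke_hazard_survival(timeline_a, ages)$h
  hb <- stroke_hazard_survival(timeline_b, ages)$h
  if (any(hb == 0))
    stopf("reference hazard is zero at some requested ages")
  data.frame(age = ages, rr = ha / hb)
}
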