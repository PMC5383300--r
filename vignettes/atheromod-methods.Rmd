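---
title: "Methods: a mechanistic cell-count model of atherosclerosis for cohort likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mechanistic cell-count model of atherosclerosis for cohort likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atheromod)
```

## The disease model and its assumptions

`atheromod` treats the atherosclerotic lesion as a population of
independent cells. Monocytes enter the arterial wall as a Poisson stream
with rate $N\nu_0$ (the monocyte count $N$ and per-monocyte uptake rate
$\nu_0$ are never separated — only their product is identifiable) and
become macrophages. A macrophage proliferates at rate $\alpha$, dies or
emigrates at rate $\beta$, and ingests lipid to become a foam cell at
rate $\nu_1$. Foam cells do not proliferate and their debris is cleared
inefficiently, so the state $F$ counts foam cells *and* debris and never
shrinks except by the last transition: with a very small rate $\nu_2$
per foam cell, a lesion converts into a *vulnerable plaque* that leads
to first stroke exactly $t_{lag}$ years later.

Key modelling assumptions, stated explicitly:

* **Independent lineages.** Cells do not interact; there is no spatial
  structure, no lesion geometry, no smooth-muscle or lipid compartment.
  Independence is what makes the likelihood computable exactly.
* **Identifiability conventions.** $\alpha$ is fixed at 12/y (its value
  trades off against $\beta$ and $\nu_1$), $\nu_2$ at $10^{-7}$/y (only
  $\nu_1\nu_2$ is identifiable while $\nu_2 \ll 1$/y), $t_{lag}$ at
  10 y. The *effective proliferation rate*
  $\gamma = \alpha - \beta - \nu_1$ is the stored parameter; $\beta$ is
  derived and must be non-negative. $\gamma$ itself may be negative (a
  shrinking macrophage population); the default fitting box keeps it in
  $[0.1, 0.3]$/y, alongside $N\nu_0 \in [1, 10]$/y and
  $\nu_1 \in [0.1, 12]$/y. The box admits corners with
  $\gamma + \nu_1 > \alpha$; these are rejected as infeasible
  ($\beta < 0$) and the optimizer sees an effectively infinite deviance
  there.
* **Deterministic lag.** The plaque-to-stroke delay is a constant, not a
  random variable; competing death during the lag is handled as
  censoring in the likelihood, not inside the survival function.

Rates can be modulated three ways, composed in the fixed order *age law
→ categorical multipliers → dose factor* (multiplicative factors
commute, so the order matters only for error attribution): a regularized
power law $\eta(a) = \eta(a_0)\,((a+10)/(a_0+10))^{\psi}$ with
$\psi \in [-1,1]$ and conventional reference ages $a_0$ (10 y for
$N\nu_0$, 40 y for $\alpha,\gamma,\nu_1$, 60 y for $\nu_2$); per-category
multipliers with the reference category pinned at 1; and linear
radiation factors $\eta = \eta(0)(1+\lambda d)$ in cumulative dose or
$\eta(0)(1+\lambda r)$ in annual dose rate, rejected (not clamped) when
$1 + \lambda x \le 0$.

## From the master equation to two ODEs

The full probability law of $(M, F, R)$ is an infinite ODE system, but
lineage independence collapses it. Let $v(s,t)$ be the probability that
a single foam cell present at age $s$ has seeded no plaque by $t$:
$v = \exp(-\int_s^t \nu_2)$. Let $u(s,t)$ be the same probability for a
single macrophage and all of its descendants. First-step analysis gives
the backward Riccati equation

$$\frac{\partial u}{\partial s}
  = (\alpha+\beta+\nu_1)\,u - \alpha u^2 - \beta - \nu_1 v, \qquad
  u(t,t) = 1 .$$

Poisson immigration then thins: the first-plaque survival is
$S_R(t) = \exp(-\int_0^t N\nu_0(s)(1-u(s,t))\,ds)$, stroke-free survival
$S(a) = S_R(a - t_{lag})$, and the hazard is the $t$-derivative of
$-\ln S_R$ shifted by the lag. These formulas are *derived here from
first principles* and validated in two independent ways: against the
closed form available when $\alpha = \beta = 0$ (a two-exponential race,
matched to $10^{-6}$), and against the stochastic simulator (agreement
within 3 binomial standard errors at ages 30/50/70 for parameter sets
spanning the fitting box with $\nu_2 \in \{10^{-7},10^{-5},10^{-3}\}$/y).

**Numerical strategy.** Parameter timelines are piecewise constant on
annual intervals (matching annual dose records and the 1-year likelihood
grid; age laws are discretized at interval midpoints). Two solver paths:

* *Time-homogeneous* (constant rates — the common case, including every
  covariate stratum without age laws or dose response): $u(s,t)=U(t-s)$,
  and a single forward `lsoda` solve of $U$ augmented with the integral
  state $I(\tau) = \int_0^\tau (1-U)$ yields
  $S_R = e^{-N\nu_0 I}$ and the *exact* hazard
  $h_R(\tau) = N\nu_0(1-U(\tau))$, with solver output only at the
  requested ages. Tolerances $10^{-8}$ (relative) / $10^{-10}$
  (absolute).
* *Age-inhomogeneous*: one backward sweep of $(u, v)$ per horizon, exact
  per-interval integration with trapezoidal quadrature (0.25-y nodes) of
  the immigration integral. The hazard defaults to central finite
  differences of $-\ln S_R$ with step 0.05 y; an augmented backward ODE
  for $\partial u/\partial t$ provides the exact derivative and is used
  as a cross-check in the tests.

The internal identity $\exp(-\int_0^a h) = S(a)$ holds to relative error
below $10^{-4}$ on a 0.25-y grid, and halving the likelihood grid step
moves a fixed synthetic cohort's deviance by well under one point.

## The Monte-Carlo simulator

The simulator updates $(M, F, R)$ 365 times per year by default. Each
step draws independent Poisson counts for influx, births, deaths,
foam-cell conversions (computed from the state at step start — a
parallel update avoiding order artifacts) and plaque seedings; $M$ and
$F$ are floored at zero (flooring is rare at the default step). A plaque
seeding consumes one foam cell, preserving the conservation identity
that every conversion moves exactly one cell. Aggregate Poisson draws
per transition are equivalent in distribution to per-cell simulation in
the small-step limit and cost O(1) per step. Rates are re-evaluated once
per simulated year, matching the solver's annual grid.

Replicates are simulated as vectorized state arrays under a single
seeded stream: one `set.seed` call makes the whole batch reproducible,
and vectorizing across replicates is orders of magnitude faster in R
than per-replicate loops with derived seeds (the per-trajectory
`simulate_individual` keeps its own seed argument). Lesion prevalence
curves report, per annual age and threshold, the fraction of replicates
whose *current* $M+F$ is at least the threshold — current counts, not
running maxima, because small accumulations may regress.

## The cohort likelihood

Each worker contributes
$l_i = \frac{S(a_{i,\mathrm{out}})}{S(a_{i,\mathrm{in}})}
\,[h(a_{i,\mathrm{out}})]^{\delta_i}$ — left truncation at entry into
follow-up, right censoring at exit, the hazard factor only for cases.
Normalization constants are dropped; they cancel in deviance
differences. Survival is interpolated log-linearly between the annual
grid nodes; a case at an age where the model hazard vanishes yields a
$-\infty$ contribution that is reported (worker ids attached), never
silently dropped. Workers sharing a realized parameter timeline share
one survival grid; the deduplication is by value (a hash of the
timeline), so deviances with and without caching agree to $10^{-8}$.

Two variables without a biological interpretation — calendar year and
graduation — can enter the mechanistic fit only as multiplicative
factors on the *hazard* (a piecewise-linear log-hazard in calendar year
and per-category factors). The exact construction used alongside the
original mechanistic analyses is not recoverable from the main text of
the source literature, so this multiplicative-hazard treatment is a
documented reconstruction; it integrates the scaled hazard over each
worker's follow-up year by year. "Unknown" covariate categories are
separate levels with their own multipliers.

**Fitting.** The deviance is minimized by `stats::nlminb` (bounded
quasi-Newton) in box-scaled coordinates from several seeded starts.
This likelihood has long, gently curved ridges — $N\nu_0$, $\gamma$ and
$\nu_1$ trade off strongly, which is visible in the width of their
intervals — and finite-difference quasi-Newton steps stall on them, so
the optimizer alternates with a derivative-free Nelder–Mead stage until
the deviance stops improving; one-parameter fits use golden-section
search instead. Infeasible points ($\beta<0$, non-positive dose factor,
zero-hazard case) return a large finite deviance. Convergence is
declared when a restart from the best point improves by less than
$10^{-3}$.

**Profile intervals.** 95% intervals are the points where the profiled
deviance (re-optimizing all other free parameters, warm-started from the
neighbouring profile point plus a short simplex pass) exceeds the
minimum by $\chi^2_1(0.95) = 3.84$, found by a bracketed walk toward
each box bound and `uniroot`. Bounds truncated by the box are flagged
boundary-censored. Likelihood-ratio tests use the upper
$\chi^2_{df}$ tail; on null synthetic cohorts the deviance gain of one
spurious modifier parameter is distributed as $\chi^2_1$
(Kolmogorov–Smirnov check in the test suite).

## The empirical baseline

The descriptive reference model is a log-linear hazard, piecewise linear
in age (knots 40/60 y, 3 slope parameters plus a global intercept) and
calendar year (knots 1970/1990, 3 parameters, linear already before the
first knot), with multiplicative covariate factors and an excess
relative risk $(1+\lambda d)$ applied only below an age cutoff $\mu$
($\mu \to \infty$ recovers the age-independent one-parameter variant).
The spline basis, knot placement and the choice of age rather than
log-age are reconstructions — the reference literature's exact basis is
not recoverable — with knots as configuration values; $\mu$ is profiled
on a 1-y grid because the likelihood is piecewise constant in it, and
its extra nuisance parameter means radiation significance cannot be read
off the $\chi^2_1$ table. Within a year, cumulative dose is held at its
start-of-year value, matching the annual parameter grid; segment
integrals of the exponential-linear hazard are computed in closed form,
so the empirical survival is exact. By construction the hazard ratio
between covariate categories is the same at every age — the structural
contrast with the mechanistic model, where a multiplier on $\nu_2$
yields a ratio that starts at the multiplier just above $t_{lag}$ and
declines with age because exposed workers with advanced lesions leave
the risk set earlier.

## The synthetic-cohort generator

The generator emulates the structure of a mid-century male occupational
cohort as consumed by the likelihood: hire years uniform on 1948–1972;
entry ages truncated-normal (mean 25 y, sd 7 y, range 18–60 y);
employment durations truncated-normal (mean 18 y, sd 12 y, capped at 45
y and at the administrative end); covariates drawn at entry (smoker or
ex-smoker 65%, hypertensive 20%, higher education 15%, with small
"unknown" fractions). Annual doses are lognormal during employment with
a between-worker log-sd of 1.2 and between-year log-sd of 0.5, an
early-era multiplier $e^{0.15\,\max(1963-y,\,0)}$ reflecting higher
doses in early plant operation, and a global scale solved numerically so
the sample median cumulative dose hits 0.28 Gy; at full cohort scale
(14,056 workers) about 7–8% of workers exceed 2 Gy. Censoring is the
minimum of Gompertz other-cause mortality (level $1.6\times10^{-4}$/y,
log-slope 0.09/y — roughly a median male lifespan near 70 y),
exponential emigration (0.02/y) and the administrative cutoff at the end
of 2008; these were chosen so a full-scale cohort produces on the order
of 22 person-years per worker and 3.5–4.5 stroke cases per 1000
person-years. All of these are assumptions standing in for confidential
cohort data, not published facts; the entry-age and duration
distributions in particular are undocumented anywhere and are package
choices.

Stroke ages are drawn by inverse-CDF sampling from the generating
model's own survival function, *conditional on being stroke-free at
entry* (uniform draws rescaled by $S(a_{in})$) — exactly the
left-truncation the likelihood assumes. The stochastic-simulator path is
retained as an alternative so generator and solver remain falsifiable
against each other (their stroke-age distributions agree by
Kolmogorov–Smirnov test). Censoring is drawn independently of the latent
cell state, i.e. non-informative. Pre-employment health selection (a
hiring examination excluding persons with advanced disease) is *not*
modelled; real cohorts may therefore show depressed risk at young
attained ages that synthetic cohorts will not reproduce. Every generated
cohort carries a truth manifest (parameters, design, seed) that
round-trips through JSON and can rebuild the generating model.

What passing recovery tests on these cohorts shows — and what it does
not: they demonstrate that the likelihood machinery, solver and profiles
are internally correct and that the three free biological parameters are
recoverable at realistic case counts under the model's own assumptions.
They cannot show that the model is correctly specified for real cohort
data, where selection effects, informative censoring, dose-measurement
error and time-varying covariates (blood pressure measured once at
hire) all violate the generator's idealizations.

## Problem sizes and runtime choices

The test suite exercises: simulator–solver agreement at 2000 replicates
per parameter set (365 steps/year); profile-interval coverage for
$\gamma$ over 20 cohorts of 10,000 workers each (roughly 1000 cases per
cohort); likelihood-ratio calibration over 200 null cohorts of 600
workers; and smaller property checks. These sizes keep the full suite in
the tens of minutes on one core while leaving Monte-Carlo error well
below the tolerances being asserted. The deviance of a 10,000-worker
homogeneous cohort evaluates in under 10 ms because the solver reduces
to a single two-state ODE solve.

## Known limitations

* Per-worker dose responses make every exposed worker their own stratum;
  fitting a dose response is therefore quadratic-feeling in practice and
  intended for moderate cohort sizes (the scan machinery fits one
  candidate at a time).
* The hazard of the inhomogeneous path relies on finite differences by
  default; the augmented exact derivative is available and test-verified
  but roughly three times the cost.
* `predict()` on fits with surrogate hazard factors returns the
  biological-stratum curves without the surrogate factor (a warning is
  emitted).
* Profile intervals at box bounds are reported censored rather than
  extrapolated; with the default $\gamma$ box this happens regularly at
  the lower edge, and is informative rather than pathological given the
  deliberate tightness of that range.
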