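# Shared fixtures, built in code.

# Best-fit biological rates of the age-independent mechanistic analysis.
reference_fit_rates <- function() rate_set(nu0N = 4.5, gamma = 0.12, nu1 = 1.3)

# Baseline parameter set of the lesion-prevalence simulation study.
prevalence_study_rates <- function(nu2 = 1e-7)
  rate_set(nu0N = 3, gamma = 0.2, nu1 = 1, alpha = 12, nu2 = nu2,
           t_lag = 10)

# A tiny hand-built cohort: three censored workers and one case.
tiny_cohort <- function() {
  workers <- data.frame(
    id = c("a", "b", "c", "d"),
    birth_year = c(1930, 1935, 1940, 1928),
    age_in = c(20, 25, 22.5, 30),
    age_out = c(60, 55.25, 40, 70),
    event = c(0L, 0L, 0L, 1L),
    smoking = c("nonsmoker", "smoker_or_ex", "unknown", "smoker_or_ex"),
    blood_pressure = c("normal", "hypertensive", "normal", "unknown"),
    graduation = c("none", "higher", "none", "none"),
    stringsAsFactors = FALSE)
  doses <- data.frame(id = c("b", "b", "b"),
                      calendar_year = c(1960, 1961, 1962),
                      dose_gy = c(0.2, 0.1, 0.05))
  stroke_cohort(workers, doses)
}

# Small synthetic cohort generated once per session (moderate event count).
small_synth <- local({
  cache <- NULL
  function(n = 1200, seed = 42, truth = reference_fit_rates()) {
    key <- paste(n, seed)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      g <- generate_cohort(cohort_design(n, truth, seed = seed))
      attr(g, "key") <- key
      cache <<- g
    }
    cache
  }
})
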