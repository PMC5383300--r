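# Cohort container and CSV IO.
#
# A cohort is one row per worker (follow-up window in age-time, event
# indicator, categorical covariates, birth year for calendar linkage) plus
# a long-format table of annual external gamma-dose records. Ages are
# decimal years; calendar years are integers; the dose within calendar year
# y is attributed to the age interval [y - birth_year, y - birth_year + 1).

covariate_levels <- list(
  smoking        = c("nonsmoker", "smoker_or_ex", "unknown"),
  blood_pressure = c("normal", "hypertensive", "unknown"),
  graduation     = c("higher", "none", "unknown"))

#' Occupational cohort for stroke-incidence analysis
#'
#' @param workers data.frame with columns \code{id}, \code{birth_year},
#'   \code{age_in}, \code{age_out}, \code{event} (0/1), \code{smoking},
#'   \code{blood_pressure}, \code{graduation}.
#' @param doses data.frame with columns \code{id}, \code{calendar_year},
#'   \code{dose_gy} (annual external gamma dose); workers without dose rows
#'   have a zero-dose history.
#' @return An object of class \code{stroke_cohort}. Person-years and case
#'   counts are always recomputed from the records, never trusted from
#'   input.
#' @export
stroke_cohort <- function(workers,
                          doses = data.frame(id = character(),
                                             calendar_year = integer(),
                                             dose_gy = numeric())) {
  need <- c("id", "birth_year", "age_in", "age_out", "event",
            names(covariate_levels))
  miss <- setdiff(need, names(workers))
  if (length(miss))
    stopf("worker table lacks column(s): %s", paste(miss, collapse = ", "))
  workers <- as.data.frame(workers)[need]
  workers$id <- as.character(workers$id)
  if (anyDuplicated(workers$id)) stopf("duplicate worker ids")
  bad <- which(!(workers$age_in < workers$age_out))
  if (length(bad))
    stopf("age_in >= age_out for worker row(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (any(workers$age_in < 0)) stopf("negative age_in")
  if (!all(workers$event %in% c(0, 1)))
    stopf("'event' must be 0 or 1")
  for (cv in names(covariate_levels)) {
    workers[[cv]] <- as.character(workers[[cv]])
    bad <- which(!workers[[cv]] %in% covariate_levels[[cv]])
    if (length(bad))
      stopf("unknown %s category '%s' (row %d)", cv,
            workers[[cv]][bad[1]], bad[1])
  }
  doses <- as.data.frame(doses)
  needd <- c("id", "calendar_year", "dose_gy")
  if (!all(needd %in% names(doses)))
    stopf("dose table needs columns: %s", paste(needd, collapse = ", "))
  doses <- doses[needd]
  doses$id <- as.character(doses$id)
  if (any(doses$dose_gy < 0)) stopf("negative annual dose")
  orphan <- setdiff(doses$id, workers$id)
  if (length(orphan))
    stopf("dose rows without matching worker: %s",
          paste(utils::head(orphan, 5), collapse = ", "))
  structure(list(workers = workers, doses = doses),
            class = "stroke_cohort")
}

#' @export
print.stroke_cohort <- function(x, ...) {
  cat(sprintf("Stroke cohort: %d workers, %.0f person-years, %d cases\n",
              nrow(x$workers), person_years(x), n_cases(x)))
  invisible(x)
}

#' Total follow-up time of a cohort
#' @param cohort A \code{\link{stroke_cohort}}.
#' @return Person-years, recomputed from the records.
#' @export
person_years <- function(cohort) {
  sum(cohort$workers$age_out - cohort$workers$age_in)
}

#' Number of stroke cases in a cohort
#' @param cohort A \code{\link{stroke_cohort}}.
#' @return Number of records with event = 1.
#' @export
n_cases <- function(cohort) sum(cohort$workers$event)

#' Read a cohort from CSV files
#'
#' @param cohort_csv Path to the worker table (one row per worker: id,
#'   birth_year, age_in, age_out, event, smoking, blood_pressure,
#'   graduation).
#' @param dose_csv Optional path to the long-format dose table (id,
#'   calendar_year, dose_gy). Omitted: all workers get zero-dose histories.
#' @return A \code{\link{stroke_cohort}}.
#' @export
read_cohort <- function(cohort_csv, dose_csv = NULL) {
  workers <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  doses <- if (!is.null(dose_csv))
    utils::read.csv(dose_csv, stringsAsFactors = FALSE)
  else data.frame(id = character(), calendar_year = integer(),
                  dose_gy = numeric())
  stroke_cohort(workers, doses)
}

#' Write a cohort to CSV files
#' @param cohort A \code{\link{stroke_cohort}}.
#' @param cohort_csv,dose_csv Output paths.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, cohort_csv, dose_csv = NULL) {
  utils::write.csv(cohort$workers, cohort_csv, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(dose_csv))
    utils::write.csv(cohort$doses, dose_csv, row.names = FALSE,
                     quote = FALSE)
  invisible(cohort)
}

# Per-worker dose history in age-time: for each worker, a list with ages
# (integer age at start of each exposed year), annual dose rate r (Gy/y)
# and cumulative dose d at the START of that age year (running integral up
# to the age considered, held piecewise constant annually).
dose_histories <- function(cohort) {
  w <- cohort$workers
  out <- vector("list", nrow(w))
  names(out) <- w$id
  empty <- list(ages = numeric(0), rate = numeric(0), cum = numeric(0))
  for (i in seq_len(nrow(w))) out[[i]] <- empty
  if (nrow(cohort$doses)) {
    split_d <- split(cohort$doses, cohort$doses$id)
    for (id in names(split_d)) {
      d <- split_d[[id]]
      d <- d[order(d$calendar_year), ]
      a <- d$calendar_year - w$birth_year[match(id, w$id)]
      out[[id]] <- list(ages = a, rate = d$dose_gy,
                        cum = cumsum(c(0, d$dose_gy[-nrow(d)])))
    }
  }
  out
}

# Cumulative dose of one worker at given ages (piecewise constant annually,
# start-of-year convention).
cumulative_dose_at <- function(history, ages) {
  if (!length(history$ages)) return(rep(0, length(ages)))
  cs <- cumsum(history$rate)
  idx <- findInterval(ages, history$ages + 1)  # year i complete at age a_i+1
  ifelse(idx == 0, 0, cs[pmax(idx, 1)])
}
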