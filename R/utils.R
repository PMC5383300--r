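# Internal numerical helpers.

# Cumulative trapezoidal integral of y over x, same length as x, starting at 0.
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Derive a reproducible child seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is_number(x)) stopf("'%s' must be a single finite number", name)
  if (x < min) stopf("'%s' must be >= %g (got %g)", name, min, x)
  if (x > max) stopf("'%s' must be <= %g (got %g)", name, max, x)
  invisible(x)
}
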