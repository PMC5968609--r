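# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named simulation stage
#'
#' A single user-facing seed feeds independent named substreams (cohort,
#' preanalytics, loading, cycles, render, compare) so that re-running one
#' stage with the same seed reproduces it regardless of what ran before.
#'
#' @param seed Integer master seed.
#' @param stream Stage name, one of `"cohort"`, `"preanalytics"`, `"loading"`,
#'   `"cycles"`, `"render"`, `"compare"`.
#' @return An integer seed below 2^31.
#' @export
sub_seed <- function(seed, stream) {
  offsets <- c(cohort = 101L, preanalytics = 211L, loading = 307L,
               cycles = 401L, render = 503L, compare = 601L)
  if (!stream %in% names(offsets)) {
    stop("unknown substream: ", stream, call. = FALSE)
  }
  (abs(as.integer(seed)) %% 1000003L) * 1009L + offsets[[stream]]
}

#' Round half away from zero to a fixed number of decimals
#'
#' Percentages are printed with conventional half-up rounding (11.65 -> 11.7),
#' not the round-half-even rule of [base::round()].
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Percentage of a count pair, rounded to one decimal
#'
#' @param k Numerator count(s).
#' @param n Denominator count(s).
#' @param digits Decimal places (default 1).
#' @return `round_half_up(100 * k / n, digits)`; `NA` where `n == 0`.
#' @export
proportion_pct <- function(k, n, digits = 1) {
  out <- rep(NA_real_, length(k))
  ok <- n > 0
  out[ok] <- round_half_up(100 * k[ok] / n[ok], digits)
  out
}

# stop() with a consistent parameter-error class so callers/tests can
# distinguish configuration mistakes from data problems
param_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("chipcsf_param_error", "error")))
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    param_error(name, " must be a single probability in [0, 1]")
  }
}
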