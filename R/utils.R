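#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats plogis qlogis rnorm runif rbinom quantile sd var setNames
#' @importFrom utils packageVersion
NULL

# Display rounding used for Table-style percentages: half-up, not banker's.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half-up
#'
#' Formats `100 * num / den` the way the study tables print percentages:
#' rounded half-up to the nearest integer (so 40/170 gives 24, 124/174 gives 71).
#'
#' @param num Numerator count.
#' @param den Denominator count.
#' @param digits Digits kept after rounding (default 0).
#' @return Numeric percentage; `NA` when `den` is 0 or missing.
#' @examples
#' ghq_pct(40, 170)
#' @export
ghq_pct <- function(num, den, digits = 0) {
  out <- round_half_up(100 * num / den, digits)
  out[!is.finite(out)] <- NA_real_
  out
}

assert_prop <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must be a proportion in [0, 1].", name),
          class = "ghqwave_error")
  }
  invisible(x)
}

# Seed handling: everything random runs under withr::with_seed when a seed is
# given, so identical calls are byte-identical and the caller's RNG state is
# left untouched.
with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# First trip-return date in the emulated study; day counts are measured from it.
ghq_epoch <- function() as.Date("2018-08-12")
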