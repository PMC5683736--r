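#' Round half away from zero
#'
#' Conventional "half-up" rounding used for reported percentages and 1-d.p.
#' summaries, as opposed to the IEC 60559 banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded with ties going away from zero.
#' @examples
#' round_half_up(26.5)  # 27, where round(26.5) gives 26
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Truncated-normal sampler via inverse CDF; exact, vectorised, and stream-stable
# (consumes exactly n uniforms).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Closed-form mean of a truncated normal; used to calibrate the generator so
# arm-level population means hit their targets despite stage-wise truncation.
etnorm <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(mean)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite value in %s", what), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
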