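#' Wald (normal-approximation) control limits for a Poisson count
#'
#' Computes the Wald confidence limits `lambda +/- z * sqrt(lambda)`, where
#' `z` is the standard normal quantile at `1 - alpha/2`, evaluated at full
#' floating-point precision (not the textbook 1.96).  On a funnel plot these
#' count-scale limits are divided by `lambda` to give limits for the SMR.
#'
#' The lower limit is stored unclamped and is negative whenever
#' `lambda < z^2`; the probability of a count falling below a negative limit
#' is zero, so downstream tail-probability calculations need no special
#' casing.  Plot rendering clamps the displayed curve at zero instead.
#'
#' @param lambda Expected number of events, a positive numeric vector
#'   (need not be integer).
#' @param level Two-sided nominal level: a number in (0, 1) or a
#'   [nominal_level()] object.  Default `0.95`.
#'
#' @return A data frame of class `"smr_limits"` with one row per `lambda`
#'   and columns `lambda`, `method`, `level`, `tail_rule` (`NA` for
#'   confidence-interval methods), `lower`, `upper`.
#' @examples
#' wald_limits(10)            # roughly 3.80 to 16.20
#' wald_limits(1)$lower < 0   # TRUE: the approximation breaks down
#' @seealso [exact_limits()], [prediction_limits()]
#' @export
wald_limits <- function(lambda, level = 0.95) {
  lambda <- check_lambda(lambda)
  lv <- nominal_level(level)
  z <- stats::qnorm(1 - lv$tail_prob)
  new_smr_limits(
    lambda = lambda, method = "wald", level = lv$level, tail_rule = NA_character_,
    lower = lambda - z * sqrt(lambda),
    upper = lambda + z * sqrt(lambda)
  )
}

#' 'Exact' (chi-square) control limits for a Poisson count
#'
#' Computes the classical 'exact' Poisson interval through the chi-square
#' link: the lower limit is half the `alpha/2` quantile of a chi-square
#' distribution on `2 * lambda` degrees of freedom, and the upper limit half
#' the `1 - alpha/2` quantile on `2 * lambda + 2` degrees of freedom.
#' Non-integer `lambda` gives non-integer degrees of freedom, which
#' [stats::qchisq()] evaluates through the gamma distribution
#' (chi-square on `c` df is gamma with shape `c/2` and scale 2).
#'
#' The lower limit is strictly positive for every `lambda > 0`, so a count
#' of zero always falls below it -- the source of the very large lower-tail
#' probabilities these limits exhibit at small `lambda`.
#'
#' @inheritParams wald_limits
#' @return A data frame of class `"smr_limits"`; see [wald_limits()].
#' @examples
#' exact_limits(1)$lower   # about 0.0253, equal to -log(0.975)
#' exact_limits(c(1, 10, 100), level = 0.998)
#' @export
exact_limits <- function(lambda, level = 0.95) {
  lambda <- check_lambda(lambda)
  lv <- nominal_level(level)
  new_smr_limits(
    lambda = lambda, method = "exact", level = lv$level, tail_rule = NA_character_,
    lower = 0.5 * stats::qchisq(lv$tail_prob, df = 2 * lambda),
    upper = 0.5 * stats::qchisq(1 - lv$tail_prob, df = 2 * lambda + 2)
  )
}

#' Probability-based prediction limits for a Poisson count
#'
#' Integer control limits read directly off the Poisson(lambda) cumulative
#' distribution.  Under the conservative rule (the default), the lower
#' limit `L` is the smallest integer with `P(X <= L) >= alpha/2` and the
#' upper limit `U` the largest integer with `P(X >= U) >= alpha/2`.  An
#' observation is an outlier only when it falls *strictly* outside, so both
#' strict tail probabilities `P(X < L)` and `P(X > U)` are then at most
#' `alpha/2` -- a property that holds by construction and can be stated
#' before any data are seen.
#'
#' Because counts are discrete no integer pair attains the nominal tails
#' exactly, and the opposite convention is sometimes wanted: the
#' `"liberal"` rule shifts each limit one integer inward
#' (`L + 1`, `U - 1`), making each strict-outside tail probability at
#' *least* `alpha/2`.  The `"funnelcompar"` rule mixes the two as the Stata
#' FUNNELCOMPAR routine does: conservative below (tail at most `alpha/2`)
#' and liberal above (tail at least `alpha/2`), at the cost of asymmetric
#' behaviour in the two tails.
#'
#' For extremely small `lambda` the liberal upper limit can be `-1`
#' (when even `P(X > 0) < alpha/2`), meaning every observation falls above
#' it; this is preserved as stored rather than clamped.
#'
#' @inheritParams wald_limits
#' @param tail_rule One of `"conservative"` (default), `"liberal"`,
#'   `"funnelcompar"`; see Details.
#' @return A data frame of class `"smr_limits"` whose `lower` and `upper`
#'   are integers (stored as numeric); see [wald_limits()].
#' @examples
#' prediction_limits(10)                      # L = 4, U = 17 at 95%
#' prediction_limits(10, tail_rule = "liberal")  # L = 5, U = 16
#' @export
prediction_limits <- function(lambda, level = 0.95,
                              tail_rule = c("conservative", "liberal",
                                            "funnelcompar")) {
  lambda <- check_lambda(lambda)
  lv <- nominal_level(level)
  tail_rule <- match.arg(tail_rule)
  a2 <- lv$tail_prob

  # smallest integer with F(x) >= alpha/2: exactly stats::qpois
  L <- stats::qpois(a2, lambda)
  # largest integer x with P(X >= x) = 1 - F(x - 1) >= alpha/2.
  # q = qpois(1 - a2) is the smallest x with F(x) >= 1 - a2; U = q unless
  # F(q) lands exactly on 1 - a2, in which case q + 1 still qualifies.
  q <- stats::qpois(1 - a2, lambda)
  U <- q + as.numeric(stats::ppois(q, lambda) <= 1 - a2)

  if (tail_rule == "liberal") {
    L <- L + 1
    U <- U - 1
  } else if (tail_rule == "funnelcompar") {
    U <- U - 1
  }

  new_smr_limits(
    lambda = lambda, method = "prediction", level = lv$level,
    tail_rule = tail_rule, lower = as.numeric(L), upper = as.numeric(U)
  )
}

#' Interpolated prediction limits (for plotting only)
#'
#' The integer prediction limits produce step-function funnel curves.  For
#' display, each conservative integer limit is shifted by linear
#' interpolation of the exceeded tail probability between the two adjacent
#' integers: with `T(x) = P(X >= x)` the upper limit becomes
#' `x_U + (alpha/2 - T(x_U + 1)) / (T(x_U) - T(x_U + 1))`, which lies in
#' `[x_U, x_U + 1)`, and the lower limit is treated symmetrically with the
#' lower-tail CDF, landing in `(x_L - 1, x_L]`.  The smoothing is cosmetic:
#' because observations are integers, classification against the smoothed
#' curve is identical to classification against the raw integer limits, and
#' all probability computations in this package use the integer limits
#' only.
#'
#' @inheritParams wald_limits
#' @return A data frame of class `"smr_limits"` with real-valued limits and
#'   `method = "prediction_smoothed"`.
#' @export
interpolated_prediction_limits <- function(lambda, level = 0.95) {
  lambda <- check_lambda(lambda)
  lv <- nominal_level(level)
  a2 <- lv$tail_prob
  pl <- prediction_limits(lambda, lv, tail_rule = "conservative")
  L <- pl$lower
  U <- pl$upper

  # upper: interpolate the upper-tail probability T(x) = P(X >= x)
  T_U  <- stats::ppois(U - 1, lambda, lower.tail = FALSE)
  T_U1 <- stats::ppois(U, lambda, lower.tail = FALSE)
  upper <- U + (a2 - T_U1) / (T_U - T_U1)

  # lower: interpolate the CDF between x_L - 1 and x_L
  F_L  <- stats::ppois(L, lambda)
  F_L1 <- stats::ppois(L - 1, lambda)
  lower <- L - (F_L - a2) / (F_L - F_L1)

  new_smr_limits(
    lambda = lambda, method = "prediction_smoothed", level = lv$level,
    tail_rule = "conservative", lower = lower, upper = upper
  )
}

#' Control limits by any supported method
#'
#' Thin dispatcher over [wald_limits()], [exact_limits()] and
#' [prediction_limits()], convenient when the method is data.
#'
#' @inheritParams prediction_limits
#' @param method One of `"wald"`, `"exact"`, `"prediction"`.
#' @return A data frame of class `"smr_limits"`.
#' @export
poisson_limits <- function(lambda, method = c("wald", "exact", "prediction"),
                           level = 0.95, tail_rule = "conservative") {
  method <- match.arg(method)
  switch(method,
    wald = wald_limits(lambda, level),
    exact = exact_limits(lambda, level),
    prediction = prediction_limits(lambda, level, tail_rule)
  )
}

new_smr_limits <- function(lambda, method, level, tail_rule, lower, upper) {
  out <- data.frame(
    lambda = lambda, method = method, level = level, tail_rule = tail_rule,
    lower = lower, upper = upper,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("smr_limits", "data.frame")
  out
}
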