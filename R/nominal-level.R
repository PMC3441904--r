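#' Nominal two-sided control-limit level
#'
#' A small value object holding a two-sided coverage level together with its
#' derived quantities: `alpha = 1 - level` and the per-tail probability
#' `alpha / 2`.  Funnel plots conventionally draw 95\% "alarm" and 99.8\%
#' "action" limits; both are accepted anywhere a level is expected, as is any
#' other value strictly between 0 and 1.
#'
#' @param level Two-sided coverage, a single number in (0, 1), e.g. `0.95`.
#'
#' @return An object of class `"nominal_level"`: a list with elements
#'   `level`, `alpha` and `tail_prob` (= `alpha / 2`).
#' @examples
#' nominal_level(0.95)
#' nominal_level(0.998)$tail_prob  # 0.001
#' @export
nominal_level <- function(level) {
  if (inherits(level, "nominal_level")) {
    return(level)
  }
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop("'level' must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  structure(
    list(level = level, alpha = 1 - level, tail_prob = (1 - level) / 2),
    class = "nominal_level"
  )
}

#' @export
print.nominal_level <- function(x, ...) {
  cat(sprintf("<nominal level %g%%: alpha = %g, per-tail %g>\n",
              100 * x$level, x$alpha, x$tail_prob))
  invisible(x)
}

# Validate a vector of Poisson means (expected event counts).
check_lambda <- function(lambda, arg = "lambda") {
  if (!is.numeric(lambda) || length(lambda) < 1L) {
    stop(sprintf("'%s' must be a non-empty numeric vector", arg),
         call. = FALSE)
  }
  if (anyNA(lambda) || any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop(sprintf("'%s' must contain finite values > 0 (expected event counts)",
                 arg), call. = FALSE)
  }
  as.numeric(lambda)
}

#' Methods available for control-limit construction
#'
#' @return Character vector of the supported method names.
#' @export
limit_methods <- function() c("wald", "exact", "prediction")

#' Tail rules for prediction limits
#'
#' `"conservative"` keeps each strict-outside tail probability at or below
#' the nominal `alpha/2`; `"liberal"` keeps each at or above it;
#' `"funnelcompar"` mixes the two (conservative below, liberal above), as
#' the Stata FUNNELCOMPAR routine does.
#'
#' @return Character vector of the supported tail-rule names.
#' @export
tail_rules <- function() c("conservative", "liberal", "funnelcompar")
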