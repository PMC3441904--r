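#' True tail probabilities of falling outside control limits
#'
#' For each limit pair, computes the exact probability that an in-control
#' observation `X ~ Poisson(lambda)` falls *strictly* outside:
#' `p_below = P(X < lower)` and `p_above = P(X > upper)`.  An observation
#' exactly on a limit is inside.  Because `X` is integer-valued,
#' `P(X < l) = F(ceiling(l) - 1)` and `P(X > u) = 1 - F(floor(u))`, which
#' handles real-valued confidence limits, integer prediction limits and
#' negative Wald lower limits (probability zero) uniformly.
#'
#' These are the quantities a funnel-plot user implicitly assumes equal the
#' nominal `alpha/2`; for discrete counts they rarely do.
#'
#' @param limits An `"smr_limits"` data frame from [wald_limits()],
#'   [exact_limits()], [prediction_limits()] or [poisson_limits()].
#' @return A data frame of class `"smr_coverage"`: the input columns plus
#'   `p_below` and `p_above`.
#' @examples
#' tail_probabilities(exact_limits(1))       # p_below = exp(-1) = 0.3679
#' tail_probabilities(prediction_limits(10)) # p_above = P(X > 17) = 0.014
#' @export
tail_probabilities <- function(limits) {
  check_smr_limits(limits)
  if (any(limits$method == "prediction_smoothed")) {
    stop("smoothed prediction limits are for plotting only; ",
         "compute tail probabilities from the integer prediction limits",
         call. = FALSE)
  }
  out <- limits
  out$p_below <- stats::ppois(ceiling(limits$lower) - 1, limits$lambda)
  out$p_above <- stats::ppois(floor(limits$upper), limits$lambda,
                              lower.tail = FALSE)
  class(out) <- c("smr_coverage", "data.frame")
  out
}

#' Sweep true tail probabilities over a grid of expected counts
#'
#' @param lambda Positive numeric vector of expected event counts, the grid.
#' @param method One of `"wald"`, `"exact"`, `"prediction"`.
#' @param level Two-sided nominal level in (0, 1).
#' @param tail_rule Tail rule for prediction limits; ignored otherwise.
#' @return An `"smr_coverage"` data frame, one row per grid value, in grid
#'   order.
#' @examples
#' coverage_grid(1:50, "wald", 0.95)
#' @export
coverage_grid <- function(lambda, method, level = 0.95,
                          tail_rule = "conservative") {
  lambda <- check_lambda(lambda)
  tail_probabilities(poisson_limits(lambda, method, level, tail_rule))
}

#' Default expected-count bins used for range summaries
#'
#' The conventional reporting bins: 1-50, >50-100, >100-500, >500-1000 and
#' >1000-10000.  Each bin covers `min < lambda <= max`, except the first,
#' which also includes its lower edge.
#'
#' @return A data frame with columns `label`, `min`, `max`, `min_inclusive`.
#' @export
smr_bins <- function() {
  data.frame(
    label = c("1-50", ">50-100", ">100-500", ">500-1000", ">1000-10000"),
    min = c(1, 50, 100, 500, 1000),
    max = c(50, 100, 500, 1000, 10000),
    min_inclusive = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default grid of expected counts for coverage sweeps
#'
#' A fine sweep of `lambda` from 1 to 10,000.  Tail probabilities change
#' rapidly at small expected counts, where the integer limits jump at every
#' crossing of the CDF, so the grid uses step `1e-4` up to `lambda = 50`
#' and step `0.01` beyond; range summaries (medians and especially minima
#' and maxima, which live at the jump points) are then stable to the fourth
#' decimal place.
#'
#' @param max Upper end of the sweep (default 10000).
#' @param fine_until Boundary between the fine and coarse steps (default 50).
#' @param fine_step,step Grid steps below and above `fine_until`.
#' @return A numeric vector of expected counts.
#' @export
default_lambda_grid <- function(max = 10000, fine_until = 50,
                                fine_step = 1e-4, step = 0.01) {
  if (max <= fine_until) {
    return(seq(1, max, by = fine_step))
  }
  c(seq(1, fine_until, by = fine_step),
    seq(fine_until + step, max, by = step))
}

#' Summarise tail probabilities over ranges of the expected count
#'
#' Bins coverage records by `lambda` and reports, for each bin and tail,
#' the median, minimum and maximum of the true tail probability.  The
#' median of an even number of values is the mean of the central pair.
#'
#' @param records An `"smr_coverage"` data frame from [coverage_grid()] or
#'   [tail_probabilities()]; may mix methods and levels.
#' @param bins A bin table as returned by [smr_bins()] (the default).
#' @return A data frame with columns `range`, `method`, `level`, `tail`
#'   (`"lower"` or `"upper"`), `median`, `min`, `max`, ordered by
#'   level, method, tail, bin.  Every record must fall in exactly one bin.
#' @examples
#' g <- coverage_grid(1:100, "exact", 0.95)
#' summarize_ranges(g, smr_bins()[1:2, ])
#' @export
summarize_ranges <- function(records, bins = smr_bins()) {
  if (!is.data.frame(records) ||
      !all(c("lambda", "method", "level", "p_below", "p_above") %in%
           names(records))) {
    stop("'records' must be a coverage data frame from coverage_grid() ",
         "or tail_probabilities()", call. = FALSE)
  }
  if (nrow(records) == 0L) stop("'records' is empty", call. = FALSE)

  bin_of <- rep(NA_integer_, nrow(records))
  for (b in seq_len(nrow(bins))) {
    lo_ok <- if (bins$min_inclusive[b]) records$lambda >= bins$min[b]
             else records$lambda > bins$min[b]
    hit <- lo_ok & records$lambda <= bins$max[b]
    if (any(hit & !is.na(bin_of))) {
      stop("bins overlap: some lambda values fall in more than one bin",
           call. = FALSE)
    }
    bin_of[hit] <- b
  }
  if (anyNA(bin_of)) {
    stop(sprintf("%d record(s) fall outside all bins (e.g. lambda = %g)",
                 sum(is.na(bin_of)), records$lambda[which(is.na(bin_of))[1]]),
         call. = FALSE)
  }

  keys <- unique(records[, c("method", "level")])
  out <- list()
  for (k in seq_len(nrow(keys))) {
    sel_k <- records$method == keys$method[k] & records$level == keys$level[k]
    for (b in seq_len(nrow(bins))) {
      sel <- sel_k & bin_of == b
      if (!any(sel)) next
      for (tail in c("lower", "upper")) {
        p <- if (tail == "lower") records$p_below[sel] else records$p_above[sel]
        out[[length(out) + 1L]] <- data.frame(
          range = bins$label[b], method = keys$method[k],
          level = keys$level[k], tail = tail,
          median = stats::median(p), min = min(p), max = max(p),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$level, out$method, out$tail), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Range summary of true tail probabilities for all methods and levels
#'
#' Convenience wrapper that sweeps the default fine grid of expected counts
#' for every requested method and level, and tabulates the median, minimum
#' and maximum true outside-probability per tail and per `lambda` range --
#' the full comparison table for the three limit-construction methods.
#'
#' @param methods Character vector of methods (default all three).
#' @param levels Numeric vector of two-sided levels (default 0.95 and 0.998).
#' @param lambda Grid of expected counts (default [default_lambda_grid()]).
#' @param bins Bin table (default [smr_bins()]).
#' @param tail_rule Tail rule for the prediction method.
#' @param digits Round the summary columns to this many decimals
#'   (default 4, as conventionally printed); `NULL` for full precision.
#' @return A data frame as from [summarize_ranges()]; with the defaults,
#'   2 levels x 3 methods x 2 tails x 5 bins = 60 rows.
#' @examples
#' \donttest{
#' coverage_table(lambda = default_lambda_grid(max = 100))
#' }
#' @export
coverage_table <- function(methods = limit_methods(),
                           levels = c(0.95, 0.998),
                           lambda = default_lambda_grid(),
                           bins = smr_bins(),
                           tail_rule = "conservative",
                           digits = 4) {
  methods <- match.arg(methods, limit_methods(), several.ok = TRUE)
  pieces <- list()
  for (level in levels) {
    for (method in methods) {
      pieces[[length(pieces) + 1L]] <-
        coverage_grid(lambda, method, level, tail_rule)
    }
  }
  records <- do.call(rbind, pieces)
  out <- summarize_ranges(records, bins)
  if (!is.null(digits)) {
    for (col in c("median", "min", "max")) out[[col]] <- round(out[[col]], digits)
  }
  out
}

#' Monte-Carlo check of the analytic tail probabilities
#'
#' Draws `n_draws` Poisson(lambda) counts, classifies each against the
#' limits with the same strict-outside convention as
#' [tail_probabilities()], and returns the observed outside fractions.
#' Used to cross-check the analytic values; agreement is within binomial
#' sampling error.
#'
#' @inheritParams coverage_grid
#' @param lambda A single positive expected count.
#' @param n_draws Number of simulated counts, at least 1.
#' @param seed Integer seed; required, so every run is reproducible.
#' @return A one-row data frame with columns `lambda`, `method`, `level`,
#'   `tail_rule`, `n_draws`, `p_below`, `p_above`.
#' @examples
#' empirical_coverage(10, "prediction", 0.95, n_draws = 1e4, seed = 1)
#' @export
empirical_coverage <- function(lambda, method, level = 0.95,
                               n_draws, seed, tail_rule = "conservative") {
  lambda <- check_lambda(lambda)
  if (length(lambda) != 1L) stop("'lambda' must be a single value", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.numeric(n_draws) || length(n_draws) != 1L || n_draws < 1 ||
      n_draws != round(n_draws)) {
    stop("'n_draws' must be a positive integer", call. = FALSE)
  }
  lim <- poisson_limits(lambda, method, level, tail_rule)
  set.seed(as.integer(seed))
  x <- stats::rpois(n_draws, lambda)
  data.frame(
    lambda = lambda, method = lim$method, level = lim$level,
    tail_rule = lim$tail_rule, n_draws = as.integer(n_draws),
    p_below = mean(x < lim$lower), p_above = mean(x > lim$upper),
    stringsAsFactors = FALSE
  )
}

check_smr_limits <- function(limits) {
  if (!is.data.frame(limits) ||
      !all(c("lambda", "method", "level", "lower", "upper") %in% names(limits))) {
    stop("expected an 'smr_limits' data frame ",
         "(from wald_limits(), exact_limits(), prediction_limits(), ...)",
         call. = FALSE)
  }
  invisible(limits)
}
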