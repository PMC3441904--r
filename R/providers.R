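#' Read a provider table from delimited text
#'
#' Expects a CSV with header columns `provider_id`, `observed`, `expected`
#' (extra columns are preserved).  `observed` must be a non-negative whole
#' number -- a value such as `"12.0"` is accepted as 12, `"12.5"` is not --
#' and `expected` must be a positive real.  Validation reports every
#' offending row and field, not just the first.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `provider_id` (character), `observed`
#'   (integer), `expected` (double), plus any extra input columns.
#' @export
read_providers <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("provider file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, strip.white = TRUE)
  required <- c("provider_id", "observed", "expected")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop(sprintf("provider file is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  validate_providers(raw)
}

# Coerce and validate provider columns (character from a file, or already
# numeric); rows reported 1-based excluding the header, matching what a
# user sees in the file.
validate_providers <- function(raw) {
  n <- nrow(raw)
  problems <- character(0)
  obs <- suppressWarnings(as.numeric(raw$observed))
  exp_ <- suppressWarnings(as.numeric(raw$expected))
  for (i in seq_len(n)) {
    if (is.na(obs[i]) || obs[i] < 0 || abs(obs[i] - round(obs[i])) > 1e-8) {
      problems <- c(problems, sprintf(
        "row %d: 'observed' must be a non-negative integer (got \"%s\")",
        i, raw$observed[i]))
    }
    if (is.na(exp_[i]) || exp_[i] <= 0) {
      problems <- c(problems, sprintf(
        "row %d: 'expected' must be a positive number (got \"%s\")",
        i, raw$expected[i]))
    }
  }
  if (length(problems) > 0L) {
    stop(paste(c("invalid provider record(s):", problems), collapse = "\n  "),
         call. = FALSE)
  }
  out <- raw
  out$provider_id <- as.character(raw$provider_id)
  out$observed <- as.integer(round(obs))
  out$expected <- exp_
  out
}

#' Write a provider table to CSV
#'
#' Writes the standard columns `provider_id,observed,expected` (plus flag
#' columns if present).  Simulation truth columns (`true_status`, `theta`)
#' are dropped unless `truth = TRUE`, so that classification code can never
#' see the simulated ground truth through the standard file format.
#'
#' @param providers A provider data frame.
#' @param path Output path.
#' @param truth Keep the simulation truth columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_providers <- function(providers, path, truth = FALSE) {
  out <- providers
  if (!truth) {
    out <- out[, setdiff(names(out), c("true_status", "theta")), drop = FALSE]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate provider tables with known in-control structure
#'
#' Generates `n_in_control` providers whose observed counts are drawn from
#' Poisson(lambda_i), i.e. whose true SMR is 1, and `n_outliers` providers
#' drawn from Poisson(theta * lambda_i) with rate ratio `theta != 1`.  The
#' expected counts `lambda_i` are either a fixed value, an explicit vector
#' (recycled across providers), or uniform draws over `lambda_range`.
#' Ground truth is stored in a `true_status` sidecar column
#' (`"in_control"` / `"outlier"`) that [write_providers()] drops by
#' default.
#'
#' @param n_in_control Number of in-control providers (>= 0).
#' @param n_outliers Number of out-of-control providers (>= 0).
#' @param theta Rate ratio for outliers, positive and different from 1;
#'   required when `n_outliers > 0`.
#' @param lambda Fixed expected count or explicit vector of expected
#'   counts; give either this or `lambda_range`.
#' @param lambda_range Length-2 range `c(a, b)` for uniform expected
#'   counts, `0 < a <= b`.
#' @param seed Integer seed; required, no silent default.
#' @return A data frame with columns `provider_id`, `observed`, `expected`,
#'   `true_status`, `theta` (1 for in-control rows).
#' @examples
#' simulate_providers(5, 2, theta = 2, lambda = 10, seed = 42)
#' @export
simulate_providers <- function(n_in_control, n_outliers = 0, theta = NULL,
                               lambda = NULL, lambda_range = NULL, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  n_in_control <- as.integer(n_in_control)
  n_outliers <- as.integer(n_outliers)
  if (is.na(n_in_control) || n_in_control < 0L ||
      is.na(n_outliers) || n_outliers < 0L) {
    stop("provider counts must be non-negative integers", call. = FALSE)
  }
  n <- n_in_control + n_outliers
  if (n == 0L) stop("nothing to simulate: all provider counts are zero",
                    call. = FALSE)
  if (n_outliers > 0L) {
    if (is.null(theta) || !is.numeric(theta) || length(theta) != 1L ||
        theta <= 0 || theta == 1) {
      stop("'theta' must be a positive rate ratio different from 1 ",
           "when simulating outliers", call. = FALSE)
    }
  }
  if (is.null(lambda) == is.null(lambda_range)) {
    stop("give exactly one of 'lambda' or 'lambda_range'", call. = FALSE)
  }

  set.seed(as.integer(seed))
  expected <- if (!is.null(lambda)) {
    lambda <- check_lambda(lambda)
    rep_len(lambda, n)
  } else {
    if (!is.numeric(lambda_range) || length(lambda_range) != 2L ||
        any(lambda_range <= 0) || lambda_range[1] > lambda_range[2]) {
      stop("'lambda_range' must be c(a, b) with 0 < a <= b", call. = FALSE)
    }
    stats::runif(n, lambda_range[1], lambda_range[2])
  }

  status <- rep(c("in_control", "outlier"), c(n_in_control, n_outliers))
  rate <- expected * ifelse(status == "outlier", theta, 1)
  data.frame(
    provider_id = sprintf("P%04d", seq_len(n)),
    observed = stats::rpois(n, rate),
    expected = expected,
    true_status = status,
    theta = ifelse(status == "outlier", theta, 1),
    stringsAsFactors = FALSE
  )
}

#' Classify providers against funnel-plot control limits
#'
#' Flags each provider as `"below"`, `"inside"` or `"above"` the control
#' limits computed at `lambda` equal to that provider's own expected count
#' (no grid binning).  The strict-outside convention is used: an observed
#' count exactly on a limit is inside.  Classification is done on the
#' count scale, which is equivalent to the SMR scale since dividing by the
#' positive expected count preserves strict inequalities.  When several
#' levels are requested the flags nest: a provider outside the wider
#' (e.g. 99.8\%) limits is necessarily outside the narrower (95\%) ones.
#'
#' @param providers Data frame with columns `provider_id`, `observed`
#'   (non-negative integers), `expected` (positive reals), e.g. from
#'   [read_providers()] or [simulate_providers()].
#' @param method Limit method (default `"prediction"`, the only method
#'   whose outside-probabilities can be bounded a priori).
#' @param levels Two-sided levels; each adds a flag column named
#'   `flag_<level>` with the leading "0." stripped (`flag_95`,
#'   `flag_998`).
#' @param tail_rule Tail rule for prediction limits.
#' @return The input data frame plus `smr` and one flag column per level.
#' @examples
#' p <- data.frame(provider_id = "A", observed = 18, expected = 10)
#' classify_providers(p)  # above the 95% prediction limit (U = 17)
#' @export
classify_providers <- function(providers, method = "prediction",
                               levels = c(0.95, 0.998),
                               tail_rule = "conservative") {
  if (!is.data.frame(providers) ||
      !all(c("provider_id", "observed", "expected") %in% names(providers))) {
    stop("'providers' must have columns provider_id, observed, expected",
         call. = FALSE)
  }
  providers <- validate_providers(providers)

  out <- providers
  out$smr <- out$observed / out$expected
  for (level in levels) {
    lim <- poisson_limits(out$expected, method, level, tail_rule)
    flag <- ifelse(out$observed < lim$lower, "below",
                   ifelse(out$observed > lim$upper, "above", "inside"))
    out[[flag_column(level)]] <- flag
  }
  out
}

flag_column <- function(level) {
  paste0("flag_", sub("^0\\.", "", format(level, trim = TRUE)))
}
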