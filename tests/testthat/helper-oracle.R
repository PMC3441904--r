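# Independent brute-force oracles, deliberately built from dpois/cumsum
# rather than the quantile functions the package uses.

# Conservative integer prediction limits by scanning the support.
oracle_prediction_limits <- function(lam, level) {
  a2 <- (1 - level) / 2
  xmax <- ceiling(lam + 20 * sqrt(lam) + 30)
  x <- 0:xmax
  cdf <- cumsum(stats::dpois(x, lam))
  upper_tail <- 1 - c(0, cdf[-length(cdf)])  # P(X >= x) for x = 0..xmax
  L <- x[which(cdf >= a2)[1]]
  U <- max(x[upper_tail >= a2])
  c(lower = L, upper = U)
}

# Strict-outside tail probabilities for arbitrary real limits, by summing
# the mass function directly.
oracle_tails <- function(lam, lower, upper) {
  xmax <- ceiling(lam + 20 * sqrt(lam) + 30)
  x <- 0:xmax
  p <- stats::dpois(x, lam)
  c(below = sum(p[x < lower]), above = 1 - sum(p[x <= upper]))
}

# A small reproducible provider table mixing in-control and shifted units.
example_providers <- function(n = 40, seed = 7) {
  set.seed(seed)
  expected <- stats::runif(n, 2, 120)
  shifted <- seq_len(n) %% 5 == 0
  data.frame(
    provider_id = sprintf("H%03d", seq_len(n)),
    observed = stats::rpois(n, expected * ifelse(shifted, 2.5, 1)),
    expected = expected,
    stringsAsFactors = FALSE
  )
}
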