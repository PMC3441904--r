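# Limit construction: Wald, exact chi-square, integer prediction limits,
# and the plotting-only interpolated variant.

z975 <- 1.9599639845400545  # standard normal 97.5th percentile (reference)

test_that("nominal levels carry exact per-tail probabilities and round-trip", {
  lv <- nominal_level(0.95)
  expect_identical(lv$tail_prob, (1 - 0.95) / 2)
  expect_identical(1 - nominal_level(0.95)$alpha, 0.95)
  expect_identical(1 - nominal_level(0.998)$alpha, 0.998)
  expect_error(nominal_level(1), "between 0 and 1")
  expect_error(nominal_level(0), "between 0 and 1")
  expect_error(nominal_level(c(0.9, 0.95)), "between 0 and 1")
})

test_that("Wald limits match the closed form at full quantile precision", {
  lim <- wald_limits(10, 0.95)
  expect_equal(lim$lower, 10 - z975 * sqrt(10), tolerance = 1e-12)
  expect_equal(lim$upper, 10 + z975 * sqrt(10), tolerance = 1e-12)
  expect_equal(round(lim$lower, 4), 3.8020)
  expect_equal(round(lim$upper, 4), 16.1980)

  # the approximation goes negative at small expected counts
  expect_lt(wald_limits(1, 0.95)$lower, 0)

  # symmetric about lambda
  lim100 <- wald_limits(100, 0.95)
  expect_equal((lim100$lower + lim100$upper) / 2, 100, tolerance = 1e-12)
})

test_that("exact limits follow the chi-square construction", {
  lim <- exact_limits(1, 0.95)
  # chi-square(2) is exponential: quantile(0.025, df=2) = -2*log(0.975)
  expect_equal(lim$lower, -log(0.975), tolerance = 1e-12)
  expect_equal(round(lim$lower, 4), 0.0253)

  # a count of zero falls below the (positive) lower limit w.p. exp(-1)
  expect_equal(oracle_tails(1, lim$lower, lim$upper)[["below"]], exp(-1),
               tolerance = 1e-12)

  # strictly positive lower limit everywhere, unlike Wald
  lams <- c(0.1, 0.5, 1, 2, 10, 100, 5000)
  expect_true(all(exact_limits(lams, 0.95)$lower > 0))

  # exact limits sit above the other two methods (lambda = 50 spot check)
  w <- wald_limits(50); e <- exact_limits(50); p <- prediction_limits(50)
  expect_gt(e$lower, w$lower)
  expect_gt(e$upper, w$upper)
  expect_gte(e$upper, p$upper)

  # non-integer lambda gives non-integer df, evaluated via the gamma link
  expect_equal(exact_limits(2.5, 0.95)$lower,
               0.5 * stats::qgamma(0.025, shape = 2.5, scale = 2),
               tolerance = 1e-12)
})

test_that("conservative prediction limits match their defining inequalities", {
  lim <- prediction_limits(10, 0.95)
  expect_identical(c(lim$lower, lim$upper), c(4, 17))
  # the defining tail statements at lambda = 10: P(X >= 17) = 0.027 >= 0.025
  # but P(X >= 18) = 0.014 < 0.025
  expect_gte(1 - ppois(16, 10), 0.025)
  expect_lt(1 - ppois(17, 10), 0.025)

  for (lam in c(0.5, 1, 2.7, 10, 31.4, 88, 200)) {
    for (level in c(0.95, 0.998)) {
      got <- prediction_limits(lam, level)
      want <- oracle_prediction_limits(lam, level)
      expect_identical(c(got$lower, got$upper), unname(as.numeric(want)),
                       label = sprintf("lambda=%g level=%g", lam, level))
    }
  }
})

test_that("brute-force scan agrees with prediction_limits across a dense grid", {
  lams <- c(seq(0.5, 20, by = 0.5), seq(21, 200, by = 7), 199.9, 200)
  for (level in c(0.95, 0.998)) {
    want <- t(vapply(lams, oracle_prediction_limits, numeric(2), level = level))
    got <- prediction_limits(lams, level)
    expect_identical(got$lower, unname(want[, 1]))
    expect_identical(got$upper, unname(want[, 2]))
  }
})

test_that("liberal and funnelcompar rules shift the conservative integers inward", {
  cons <- prediction_limits(10, 0.95)
  lib <- prediction_limits(10, 0.95, tail_rule = "liberal")
  fc <- prediction_limits(10, 0.95, tail_rule = "funnelcompar")
  expect_identical(c(lib$lower, lib$upper), c(cons$lower + 1, cons$upper - 1))
  expect_identical(c(fc$lower, fc$upper), c(cons$lower, cons$upper - 1))

  # the defining property: each liberal strict-outside tail is >= alpha/2,
  # the funnelcompar lower tail <= alpha/2 and upper tail >= alpha/2
  for (lam in c(1, 3.3, 10, 47, 120)) {
    lb <- prediction_limits(lam, 0.95, "liberal")
    tl <- oracle_tails(lam, lb$lower, lb$upper)
    expect_gte(tl[["below"]], 0.025)
    expect_gte(tl[["above"]], 0.025)
    fc <- prediction_limits(lam, 0.95, "funnelcompar")
    tf <- oracle_tails(lam, fc$lower, fc$upper)
    expect_lte(tf[["below"]], 0.025)
    expect_gte(tf[["above"]], 0.025)
  }
})

test_that("conservative tails never exceed the nominal alpha/2", {
  lams <- c(seq(0.5, 50, by = 0.5), seq(51, 200, by = 1))
  for (level in c(0.95, 0.998)) {
    a2 <- (1 - level) / 2
    cov <- tail_probabilities(prediction_limits(lams, level))
    expect_true(all(cov$p_below <= a2))
    expect_true(all(cov$p_above <= a2))
  }
})

test_that("interpolated limits bracket the integers and split the tail linearly", {
  sm <- interpolated_prediction_limits(10, 0.95)
  raw <- prediction_limits(10, 0.95)
  expect_gt(sm$upper, raw$upper)
  expect_lt(sm$upper, raw$upper + 1)
  expect_gte(sm$lower, raw$lower - 1)
  expect_lte(sm$lower, raw$lower)

  # affine relation, checked with independently summed tails
  TU <- oracle_tails(10, -1, raw$upper - 1)[["above"]]   # P(X >= U)
  TU1 <- oracle_tails(10, -1, raw$upper)[["above"]]      # P(X >= U + 1)
  expect_equal(sm$upper, raw$upper + (0.025 - TU1) / (TU - TU1),
               tolerance = 1e-12)

  # monotone in lambda
  expect_lt(interpolated_prediction_limits(10, 0.95)$upper,
            interpolated_prediction_limits(11, 0.95)$upper)
})

test_that("the three methods converge for large expected counts", {
  lam <- 10000
  w <- wald_limits(lam); e <- exact_limits(lam); p <- prediction_limits(lam)
  expect_lt(abs(w$lower - e$lower) / lam, 0.001)
  expect_lt(abs(w$upper - e$upper) / lam, 0.001)
  expect_lt(abs(w$lower - p$lower) / lam, 0.001)
  expect_lt(abs(w$upper - p$upper) / lam, 0.001)
})

test_that("99.8% limits are strictly wider than 95% limits", {
  lams <- c(1, 2.5, 10, 50, 400, 10000)
  for (method in limit_methods()) {
    l95 <- poisson_limits(lams, method, 0.95)
    l998 <- poisson_limits(lams, method, 0.998)
    expect_true(all(l998$lower <= l95$lower))
    expect_true(all(l998$upper >= l95$upper))
    expect_true(all(l998$upper - l998$lower > l95$upper - l95$lower))
  }
})

test_that("exact upper limits dominate prediction uppers for small lambda", {
  e <- exact_limits(1:50, 0.95)
  p <- prediction_limits(1:50, 0.95)
  expect_true(all(e$upper >= p$upper))
})

test_that("non-positive expected counts are rejected", {
  for (f in list(wald_limits, exact_limits, prediction_limits,
                 interpolated_prediction_limits)) {
    expect_error(f(0), "> 0")
    expect_error(f(-3), "> 0")
    expect_error(f(c(5, NA)), "> 0")
  }
})
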