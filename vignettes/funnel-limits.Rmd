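---
title: "True outside-probabilities of SMR funnel-plot control limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{True outside-probabilities of SMR funnel-plot control limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelsmr)
```

## The model and the question

A provider's outcome is a count of events (deaths, complications) whose
expected value λ comes from indirect standardisation against a reference
population. For an *in-control* provider — one whose true SMR is 1 — the
observed count is taken to be Poisson(λ). A funnel plot draws the SMR
(observed/expected) against λ with control limits at nominal two-sided
levels, conventionally 95% ("alarm") and 99.8% ("action"), and flags
providers outside them.

The implicit promise is that an in-control provider falls beyond each
limit with probability α/2 (0.025 and 0.001 respectively). Counts are
integers, so this promise cannot hold exactly for any limit, and how far
reality departs from it depends on the construction. This package
computes the departure exactly: for a limit pair (ℓ, u) at mean λ, the
true tail probabilities are

  P(below) = P(X < ℓ) = F(⌈ℓ⌉ − 1),  P(above) = P(X > u) = 1 − F(⌊u⌋),

with F the Poisson(λ) CDF.

### Boundary convention

"Outside" means *strictly* beyond a limit; a count exactly on a limit is
inside. This is the only convention under which the conservative
prediction limits below satisfy their defining bound, and it reproduces
the worst case of the 'exact' lower limit at λ = 1 (limit ≈ 0.0253 > 0,
so a zero count is outside with probability e⁻¹ ≈ 0.3679). All
classification, analytic and Monte-Carlo code in the package shares this
single convention, on the count scale; dividing by the positive expected
count shows it is equivalent to classifying on the SMR scale.

## The three constructions

**Wald**: λ ± z₁₋α/₂√λ. Quantiles are used at full floating precision;
1.96 is exposition, not the implemented constant. The lower limit is
negative for λ < z², and is stored unclamped — the probability below a
negative limit is automatically zero — with clamping applied only when a
figure is drawn.

**'Exact'**: lower = ½·χ²(α/2, 2λ), upper = ½·χ²(1 − α/2, 2λ + 2).
Expected counts are generically non-integer, so non-integer degrees of
freedom arise; they are evaluated through the gamma equivalence
(χ² on c df = gamma(shape c/2, scale 2)), which `qchisq()` provides
natively. The lower limit is strictly positive for every λ > 0.

**Prediction**: integer limits from the Poisson CDF itself. Under the
default *conservative* rule, L is the smallest integer with
F(L) ≥ α/2 and U the largest integer with P(X ≥ U) ≥ α/2; consequently
P(X < L) ≤ α/2 and P(X > U) ≤ α/2 — the one construction whose error
rates can be stated before any data are seen. The *liberal* rule shifts
both limits one integer inward (L + 1, U − 1), the unique integers making
each strict-outside tail at least α/2; the *funnelcompar* rule mixes the
two (conservative below, liberal above), trading symmetry for an upper
tail that never undershoots the nominal value. At λ = 10, level 0.95,
the three rules give (4, 17), (5, 16) and (4, 16), with upper tails
0.014, 0.027 and 0.027.

A degenerate corner: for λ < −log(1 − α/2) ≈ 0.0253 even a count of zero
has upper-tail mass below α/2, and the liberal upper limit is stored as
−1, meaning every observation falls above it. This cannot occur for the
λ ≥ 1 ranges the summaries report.

### Smoothing, quarantined

The integer prediction limits make step-function funnel curves. For
display, `interpolated_prediction_limits()` positions each limit between
the two adjacent integers by linear interpolation of the exceeded tail
probability: upper* = U + (α/2 − T(U+1)) / (T(U) − T(U+1)) with
T(x) = P(X ≥ x), and symmetrically for the lower limit with the CDF. The
smoothed value brackets the integer one, and since observations are
integers, classification against the smoothed curve is provably identical
to classification against the integers. The package enforces the
quarantine: `tail_probabilities()` refuses smoothed limits, and
`classify_providers()` never uses them. Confidence-interval limits are
always drawn raw.

## Grid resolution for the coverage summaries

`coverage_table()` summarises the true tail probabilities by λ range
(1–50, >50–100, >100–500, >500–1000, >1000–10000; the label ">a–b" means
a < λ ≤ b, and the first bin includes 1). Medians use the standard
convention (mean of the central pair for even counts) and cells are
rounded to 4 decimals.

The tail probabilities are step functions of λ with jumps wherever an
integer limit changes, so the bin summaries depend on how densely λ is
swept. An integer-stepped sweep is too coarse: it shifts the small-λ
medians visibly (e.g. the 1–50 Wald upper median moves from 0.0301 to
0.0308). `default_lambda_grid()` therefore uses step 10⁻⁴ up to λ = 50,
where the jumps are densest and the bin extrema live at jump points, and
step 0.01 beyond; at that resolution the 4-decimal cells are stable
under further refinement (the full sweep runs in well under a minute).
Two 99.8%-level cells (the >500–1000 Wald upper median, 0.00115, and the
>50–100 'exact' lower median, 0.00175) sit on a 4th-decimal rounding
boundary and are tracked at a tolerance of one unit in the fourth
decimal; every other cell, and every 95%-level headline cell, reproduces
exactly at 4 decimals.

```{r table-small}
coverage_table(lambda = default_lambda_grid(max = 100),
               bins = smr_bins()[1:2, ])
```

## What the synthetic generator does and does not emulate

`simulate_providers()` draws in-control providers as Poisson(λᵢ) and
out-of-control providers as Poisson(θλᵢ) with a user-chosen rate ratio
θ ≠ 1; expected counts λᵢ are fixed, listed explicitly, or uniform over a
range. The seed is a required argument — there is no silent default — and
ground truth lives in a sidecar column that the standard CSV writer
drops, so classification code cannot peek. This emulates exactly the
hypothesis the limits test: a provider whose true rate is the target, or
a constant multiple of it. It deliberately does *not* emulate features of
real provider data — overdispersion between providers, risk-model error
in the expected counts, correlated outcomes, multi-period data — so
passing Monte-Carlo checks here validate the probability arithmetic, not
the adequacy of the pure-Poisson model for any particular registry.

Monte-Carlo cross-checks compare observed flag rates with the analytic
tails at three binomial standard errors, with 2×10⁵ draws in the checks
tied to published values (smaller draws elsewhere for speed):

```{r mc}
empirical_coverage(10, "prediction", 0.95, n_draws = 2e5, seed = 42)
coverage_grid(10, "prediction", 0.95)[, c("p_below", "p_above")]
```

## Numerical choices and edge cases

- Integer limit search: `qpois()` implements "smallest x with
  F(x) ≥ p" directly; the upper limit adds one only when F lands exactly
  on 1 − α/2. A brute-force scan of the support is kept in the test
  suite as an independent oracle up to λ = 200.
- Tail probabilities use `ppois()` directly rather than summing mass
  functions; the test oracle does the opposite, so the two routes check
  each other to ~10⁻¹².
- Float tolerances: limits are compared at 10⁻¹⁰ or tighter; printed
  4-decimal reference values at 5×10⁻⁵ (i.e. agreement of the rounded
  value).
- Validation is strict and row-specific: observed counts must be whole
  ("12.0" is accepted as 12, "12.5" is an error naming the row),
  expected counts positive, λ positive and finite everywhere.
- 99.8% limits contain the 95% limits for every method, so action-limit
  flags are always a subset of alarm-limit flags; this nesting is
  asserted, not assumed.

## Known limitations

The 'exact' lower tail is *usually* above its nominal α/2 but not
uniformly — it dips to 0.0219 within 1 ≤ λ ≤ 50 (e.g. near λ = 21) —
so the package asserts its aggregate behaviour (bin medians above
nominal, pointwise dominance over the Wald lower tail) rather than a
false pointwise bound. Overdispersion adjustments, mid-p intervals,
multiple-testing control across providers and risk-model fitting for the
expected counts are out of scope: expected counts are taken as given,
and the target SMR is fixed at 1.
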