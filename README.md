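# funnelsmr

Funnel plots are the standard graphic for comparing institutions on a
standardised mortality ratio (SMR = observed events / expected events):
each provider's SMR is plotted against its expected event count λ, with a
target line at SMR = 1 and control limits that narrow as λ grows.
Providers outside the limits are treated as potential outliers, on the
assumption that an in-control provider (true SMR = 1, observed counts
Poisson with mean λ) falls outside a 95% limit with probability 0.05.

Because counts are discrete, that assumption is wrong to a degree that
depends strongly on how the limits are drawn. `funnelsmr` implements the
three constructions in common use and computes, exactly, the true
probability that an in-control provider is flagged by each:

- **Wald confidence limits** — λ ± z₁₋α/₂ √λ;
- **'exact' confidence limits** — ½ χ²(α/2, 2λ) below and
  ½ χ²(1 − α/2, 2λ + 2) above, via the chi-square/Poisson link
  (non-integer λ handled through the gamma equivalence);
- **probability-based prediction limits** — the smallest integer L with
  P(X ≤ L) ≥ α/2 and the largest integer U with P(X ≥ U) ≥ α/2, so that
  the strict-outside probabilities P(X < L) and P(X > U) are each at most
  α/2 *by construction* (a "conservative" rule; "liberal" and
  mixed "funnelcompar" variants are also provided).

An observation exactly on a limit counts as inside; the true tail
probabilities are then P(X < lower) and P(X > upper) read off the
Poisson CDF. The package sweeps these over fine grids of λ, summarises
median/min/max per λ range, classifies real or simulated provider tables,
draws funnel plots (with the prediction step-curves optionally smoothed by
tail-probability interpolation — display only, never used for
classification), and ships a CLI.

## Worked example

At λ = 10 and the 95% level the conservative prediction limits are the
integers 4 and 17:

```r
library(funnelsmr)
tail_probabilities(prediction_limits(10, 0.95))
#>   lambda     method level    tail_rule lower upper    p_below    p_above
#> 1     10 prediction  0.95 conservative     4    17 0.01033605 0.01427761
```

No integer cutoff attains 0.025 exactly: above 16 the tail is 0.027,
above 17 it is 0.014 — the discreteness at the heart of the problem.
Sweeping λ finely and summarising the upper 95% tail by range:

```r
tab <- coverage_table(lambda = default_lambda_grid(max = 100),
                      bins = smr_bins()[1:2, ])
subset(tab, level == 0.95 & tail == "upper")
#>      range     method level  tail median    min    max
#> 3     1-50      exact  0.95 upper 0.0121 0.0003 0.0177
#> 4  >50-100      exact  0.95 upper 0.0166 0.0129 0.0196
#> 7     1-50 prediction  0.95 upper 0.0201 0.0052 0.0250
#> 8  >50-100 prediction  0.95 upper 0.0220 0.0184 0.0250
#> 11    1-50       wald  0.95 upper 0.0301 0.0203 0.0841
#> 12 >50-100       wald  0.95 upper 0.0280 0.0247 0.0331
```

For small providers the nominal 0.025 is a fiction: Wald limits flag an
in-control provider above the upper limit with median probability 0.0301
(up to 0.0841), the 'exact' limits with only 0.0121, and the prediction
limits — the only method whose error rate can be bounded a priori — with
0.0201, never exceeding 0.0250.

Classifying a simulated provider table (two providers with true rate
ratio 2.2 among 18 in-control ones):

```r
sim <- simulate_providers(n_in_control = 18, n_outliers = 2, theta = 2.2,
                          lambda_range = c(5, 80), seed = 10)
flagged <- classify_providers(sim)
flagged[flagged$flag_95 != "inside", ]
#>    provider_id observed expected      smr flag_95 flag_998 true_status
#> 19       P0019       74 34.90930 2.119779   above    above     outlier
#> 20       P0020      134 67.71006 1.979026   above    above     outlier
```

The same operations are available from the shell via `exec/funnelsmr`:
`limits`, `coverage-table`, `funnel`, `classify`, `simulate`
(run any subcommand with `--help`).

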