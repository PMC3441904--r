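Package: funnelsmr
Title: Funnel-Plot Control Limits and True Coverage for the Standardised
    Mortality Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Constructs funnel-plot control limits for the standardised
    mortality ratio (SMR) under a Poisson model by three methods in common
    use: the Wald (normal approximation) confidence interval, the 'exact'
    confidence interval obtained from chi-square quantiles, and
    probability-based prediction limits read directly off the Poisson
    cumulative distribution.  Because event counts are discrete, the true
    probability that an in-control provider falls outside a limit differs
    from the nominal tail probability; the package computes these true tail
    probabilities exactly, sweeps them over grids of the expected count,
    and summarises them by range.  It also classifies observed provider
    tables against the limits, simulates provider data with known
    in-control and out-of-control structure, draws funnel plots, and ships
    a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
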