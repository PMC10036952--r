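Package: revcormem
Title: Reverse-Correlation Analysis of Perception and Perceptual Memory in
    Bistable Displays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reverse-correlation (classification-image style)
    analysis of intermittently presented bistable kinetic-depth-effect
    displays. Provides disambiguation schedules and random sequence
    generation, a synthetic two-alternative forced-choice observer with a
    known temporal kernel, probe-prime-probe triplet construction and
    outcome classification, sign-aligned per-segment averages with
    nonparametric bootstrap confidence intervals, hierarchical Bayesian
    models (a linear model with correlated random intercepts and slopes,
    and additive cubic-spline models with participant scaling weights,
    including dual-condition variants with independent, correlated, or
    identical spline weights) sampled with JAGS, Pareto-smoothed
    importance-sampling leave-one-out model comparison (ELPD), and
    percentile and highest-posterior-density interval summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    graphics,
    rjags,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
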