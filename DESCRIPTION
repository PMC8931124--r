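Package: cancelnudge
Title: Cancellation-Heuristic Framing Effects in Intertemporal Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models, simulates and analyses the effect of partitioned
    ("cancellation") framing on intertemporal choice. Implements a
    quasi-hyperbolic (beta-delta) discounted-utility model with CRRA
    curvature, indifference thresholds under integrated and partitioned
    presentation, structural estimation of time preferences from convex
    time budget allocations, seeded synthetic-agent experiment
    simulators for binary choice (gains and losses), token-allocation
    and retirement-age menu tasks, and the accompanying statistical
    layer: contingency tests, rank tests, standardized effect sizes, a
    priori power analysis, random-intercept panel logit with average
    marginal effects, and OLS moderation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
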