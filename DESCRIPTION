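Package: recoverews
Title: Early Warning Signals of Recovery for Collapsed Fish Stocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect statistical early warning signals of recovery
    in overexploited, size-structured fish stocks. Simulates
    collapse-and-release dynamics with a stochastic single-species size
    spectrum model under configurable fishing-mortality schedules; computes
    abundance-based (coefficient of variation, lag-1 autoregressive
    coefficient) and trait-based (mean and standard deviation of body size)
    stability indicators; normalizes each against its running baseline and
    sums subsets into composite metrics; flags warning signals at a sigma
    threshold under single-year and consecutive-year rules; estimates
    recovery times by single-breakpoint piecewise-constant fits; and
    evaluates detection performance (true/false positive proportions, lead
    times, ROC curves, training-length sensitivity). Includes readers for
    survey-style inputs (annual spawning-stock biomass plus individual body
    sizes) and generators for synthetic survey fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
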