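# recoverews

Early warning signals of **recovery** for collapsed, size-structured fish
stocks.

A large literature looks for statistical precursors of population
*collapse*: as a system loses resilience near a transition, its monitoring
series show rising variance and rising autocorrelation (critical slowing
down), and shifts in fitness-related traits such as body size. The same
theory predicts precursors on the way *back* — a collapsed stock that is
about to recover should signal it in advance. That is directly useful for
fisheries management: collapsed stocks are monitored closely, and knowing
whether a management intervention (here, a reduction of fishing mortality)
is working years before biomass visibly rebuilds changes what managers can
do. `recoverews` provides the full pipeline for studying this question in
simulation and applying it to survey data.

## What it computes

For an annual series of biomass $B_t$, mean body size and SD of body size
(individuals above 10 g), the package computes four indicators — CV and
AR(1) of biomass over an expanding window, plus the two trait series — and
normalizes each against its running baseline:

$$\hat w_t = \frac{w_t - \bar w_{1:t}}{\mathrm{sd}(w_{1:t})}, \qquad t \ge 2.$$

Every non-empty subset of the four indicators (15 composite metrics) is
summed per year; a warning signal of recovery fires when a composite
exceeds 2 running standard deviations, either once (single rule) or in two
consecutive years (consecutive rule). Signals during a 30-year training
window are disregarded. Per-replicate recovery years come from an
exhaustive single-breakpoint piecewise-constant fit to post-release
biomass, and the evaluation layer turns detections into true/false-positive
proportions, signal strengths, lead times, training-length sweeps and ROC
curves over thresholds 0.01–6.

The data generator is a stochastic single-species size-spectrum model
(McKendrick–von Foerster transport on a 100-class logarithmic mass grid,
explicit upwind differencing at 0.1-year sub-steps, Beverton–Holt
recruitment with annual lognormal noise) run through a burn-in / historic
ramp / 30-year collapse plateau / linear-release fishing schedule, with a
control treatment that never releases. See the methods vignette
(`vignettes/recovery-signals.Rmd`) for the model, its calibration and its
limitations.

## Worked example

Simulate a scaled-down experiment (20 replicates of the control, the
slowest and the fastest release rates), analyze it, and summarize the
headline composite:

```r
library(recoverews)

ens      <- generate_ensemble(n_reps = 20, base_seed = 101,
                              treatments = c(0, 0.02, 0.10))
analysis <- ews_analysis(ens)

s <- summarize_ensemble(analysis, rule = "single")
s[s$metric_name == "AR(1) + SD size",
  c("treatment", "n", "prop_detected", "mean_max_strength", "mean_lead")]
#>      treatment  n prop_detected mean_max_strength mean_lead
#> 1      control 20             0             0.652       NaN
#> 2 decline_0.02 20             1             5.868      26.4
#> 3  decline_0.1 20             1             7.070      15.3
```

Every release replicate shows at least one AR(1) + SD size signal above
2σ before its estimated recovery year — on average 26 years before it at
the slow release rate — while no control replicate crosses the threshold in
its 50-year window, and the control's mean maximum composite strength
(0.65σ) stays far below the threshold. The consecutive rule tells the same
story with run lengths:

```r
sc <- summarize_ensemble(analysis, rule = "consecutive")
sc[sc$metric_name == "AR(1) + SD size",
   c("treatment", "n", "prop_detected", "mean_max_run")]
#>      treatment  n prop_detected mean_max_run
#> 1      control 20             0          0.0
#> 2 decline_0.02 20             1         27.1
#> 3  decline_0.1 20             1         16.1
```

Median breakpoint recovery years are 2088 for the 2 %/yr release (fishing
reaches zero in 2090) and 2060 for the 10 %/yr release — recovery lags the
start of the release by decades, which is exactly the window in which the
signals are useful.

The survey pathway applies the same pipeline to real-style inputs (annual
SSB plus individual size records, half the years used for training):

```r
fx  <- make_survey_fixture("recovering")   # synthetic survey extract
res <- cli_survey(fx$ssb_path, fx$sizes_path, "report.csv",
                  stock = "synthetic North Sea")
res
#> <survey_ewsr> synthetic North Sea: training 1989-2003, assessment
#>   2004-2018; 14/15 metrics with consecutive signals at 2 sigma
```

A command-line wrapper over the same functions ships in
`inst/cli/recoverews.R`
(`simulate | analyze | evaluate | survey`, YAML scenario configs in
`inst/extdata/`).

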