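---
title: "Detecting early warning signals of recovery in collapsed fish stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early warning signals of recovery in collapsed fish stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recoverews)
```

## The problem

Early warning signals are statistical precursors of abrupt state changes.
Critical slowing down predicts that as a system approaches a transition its
return rate to equilibrium falls, which shows up in monitoring data as rising
variance and rising autocorrelation. The same theory applies in both
directions: a collapsed population that is about to recover should also
telegraph that recovery in advance. `recoverews` implements the full analysis
needed to study this on harvested, size-structured fish stocks: a stochastic
size-spectrum simulator that produces collapse-and-release experiments, four
stability indicators, composite z-score detection against a running baseline,
breakpoint-based recovery times, and the true/false-positive accounting that
turns per-replicate detections into performance summaries.

Two families of indicators are computed from annual survey-style data:

* **abundance-based**: the coefficient of variation (CV, a "noise" indicator)
  and the lag-1 autoregressive coefficient (AR(1), a "memory" indicator) of
  the biomass series;
* **trait-based**: the number-weighted mean and standard deviation of
  individual body size. In size-structured stocks, releasing fishing lets
  large individuals survive again, so mean size and SD size rise well before
  total biomass has rebuilt.

Each indicator series $w_t$ is normalized against its own running baseline,

$$\hat w_t = \frac{w_t - \bar w_{1:t}}{\mathrm{sd}(w_{1:t})}, \qquad t \ge 2,$$

with the sample standard deviation and the current observation included in
both running statistics. Composite metrics sum the normalized values of an
indicator subset at each time point; all 15 non-empty subsets of the four
indicators are evaluated. A warning signal fires when a composite exceeds the
threshold (2 by default, in units of running standard deviations); the
conservative variant additionally requires exceedances in two consecutive
years. Signals during a training window (the 30 collapse-period years by
default) feed the running statistics but are disregarded as detections.

## The surrogate simulator

The simulator is a single-species McKendrick-von Foerster transport model on
a 100-class logarithmic body-mass grid, advanced by explicit first-order
upwind differencing at 0.1-year sub-steps, with mortality applied as an exact
per-sub-step exponential factor:

* growth $g(w) = g_0\,w^{b}\,(1 - w/W_\infty)$ with $g_0 = 1.2$ g$^{1-b}$/yr,
  $b = 0.75$ and asymptotic mass $W_\infty = 8000$ g;
* background mortality $\mu(w) = \mu_0 w^{c}$ with $\mu_0 = 0.35$/yr and
  $c = 0$ (size-independent natural mortality);
* knife-edge fishing above 500 g, which also defines the spawner pool;
* Beverton-Holt recruitment $R = R_{\max} S/(S + S_{50})$ entering the
  smallest size class as a boundary flux, multiplied once per calendar year
  by a mean-one lognormal deviate $\exp(\sigma z - \sigma^2/2)$;
* only individuals above the 10 g observation cutoff contribute to the
  annual biomass, mean-size and SD-size records, mirroring the minimum size
  retained by trawl surveys.

Recruits enter the grid at 5 g — roughly an age-one survey recruit — rather
than at egg size. This is a numerical necessity as much as a modelling
choice: the explicit upwind scheme cannot move mass through more than one
size class per sub-step, so a milligram egg boundary would stretch the
juvenile transit to the observable window over many years and smear the
annual recruitment pulses into slow, decade-scale waves that the annual
indicators would misread. With the 5 g boundary a cohort becomes observable
within about a year, as it does in survey data.

The fishing schedule has four phases: an unfished burn-in from 1667 (by
default replaced by the deterministic equilibrium, which is identical for
every replicate and much cheaper than integrating 300 years); a linear
historic ramp from a quarter of the plateau level in 1967 to the full
plateau level in 2010; a constant-$F$ collapse plateau from 2010 to 2039;
and, from 2040, either constant $F$ (the control) or a linear release that
removes 2, 2.5, 3.3, 5 or 10 percent of the plateau level per year, reaching
zero fishing after 50, 40, 30, 20 or 10 years. The treatment list follows
the stated equivalence between percent declines and durations; note that a
literal 2.25 %/yr decline would take 45 years rather than 40, so the 40-year
treatment uses 2.5 %/yr. The schedule accepts any exact rate. An optional
peaked historic ramp (fishing overshooting the plateau before being reduced
to it) is available but off by default: a stock left below its
plateau equilibrium rebuilds slowly through the assessment era, which is a
genuine slow recovery and contaminates the control.

### Calibration

The reference experiment behind this design is a 12-species North Sea
community model whose parameterization is not reproducible from published
tables, so the single-species surrogate is calibrated to the experiment's
qualitative structure rather than copied: under the plateau the observable
stock settles below 30 % of its unfished level (28 % at the defaults);
release produces a lagged, non-linear rebuild with median breakpoint
recovery years running from the late 2080s at the slowest release rate to
about 2060 at the fastest; and mean size and SD size rise ahead of the
biomass breakpoint. The Beverton-Holt half-saturation is set to one tenth of
$R_{\max}$ times the unfished spawner-biomass-per-recruit, giving strong but
finite compensation, and the plateau fishing mortality of 1.0/yr matches the
peak exploitation rates recorded for heavily fished demersal stocks.

The recruitment noise level deserves an honest paragraph. The default is
$\sigma = 0.05$, far below the interannual recruitment variability of real
cod stocks. It was chosen so that replicate trajectories cluster tightly
around the ensemble mean, as the reference community model's replicates do:
with weak noise the deterministic collapse-era transient dominates the
training-window variance, the running baselines are wide relative to
assessment-era fluctuations, and control-era z-scores stay small. At
realistic single-species noise levels ($\sigma \approx 0.5$) the 50-year
control assessment window crosses a 2-running-SD threshold at least once in
roughly half of all replicates for trait-containing composites — a
property of scanning a long window with a stationary normalized series, not
a bug — and no parameterization we explored avoids it. Multispecies
buffering presumably supplies the missing smoothing in the reference
system. Conclusions about false-positive rates therefore transfer to real
data only to the extent that the monitored series are as smooth relative to
their training period as the simulated ones; the training-length sweep and
the ROC sweep are the right tools for exploring that sensitivity.

Two further deliberate departures are worth recording. First, recovery in
this surrogate is monotone: Beverton-Holt recruitment is purely
compensatory, so the transient overshoot that a multispecies release can
produce (prey bursts after predator removal) does not occur here; none of
the evaluated statistics depend on it. Second, the non-recovery margin used
by `recovery_time()` demands a 50 % increase in the post-break segment mean
rather than a token one: the persistently fished control erodes slowly over
the assessment era, and a smaller margin would occasionally label that drift
a recovery. The margin only classifies; TP/FP accounting always uses the
treatment labels.

## Numerical choices

* The upwind step checks the CFL number $g\,\Delta t/\Delta w$ in every
  class and refuses to integrate when it exceeds 1, naming the offending
  class.
* Expanding-window CV, AR(1) and the running z-score are computed from
  centered cumulative sums, which keeps them exact to around $10^{-12}$ even
  though biomass is of order $10^{8}$ g.
* AR(1) is the ordinary-least-squares slope (with intercept) of $x_t$ on
  $x_{t-1}$ — conditional least squares, not Yule-Walker — and is not
  clamped to $[-1, 1]$. A window with zero predictor variance returns 0 and
  is flagged.
* A running SD of exactly zero (constant series) makes $\hat w_t = 0$,
  flagged rather than infinite.
* The breakpoint search is exhaustive over admissible splits with at least
  two points per segment; ties resolve to the earliest break and are
  flagged.
* Missing indicator values (AR(1) is undefined for the first two analysis
  years) make a composite missing for that year; partial sums are never
  formed. Composites keep the raw 2-sigma threshold regardless of how many
  indicators are summed — the cited detection convention draws one
  threshold per metric — but `detection_config()` accepts any threshold,
  and a $\sqrt{k}$-rescaled threshold can be requested by passing it
  explicitly.
* The indicator windows are expanding from the analysis start year (2010)
  by default. The windowing convention behind the reference analysis is not
  stated; expanding windows are consistent with the running-baseline
  normalization, and `compute_indicator_series()` offers rolling windows as
  an alternative.
* Ensemble seeds are `base_seed + replicate`, so treatments share
  recruitment-noise streams within a replicate index; paired noise removes
  between-treatment sampling variance from the comparisons.

## Problem sizes

The package's own test suite and the bundled acceptance script run the
experiment at 50-100 replicates per treatment (the full design is 300), a
scale at which the directional results — high true-positive proportions at
the slowest release rate, single-digit control false-positive percentages,
the consecutive rule strictly more cautious than the single rule, ROC curves
monotone in the threshold — are already stable. `ensemble_plan()` and the
`paper_config.yaml` profile reproduce the full 6 x 300 = 1800-run layout.

## The survey pathway

`run_survey_ewsr()` applies the identical composite pipeline (it shares the
per-replicate code path with the simulation analysis) to real-style inputs:
an annual spawning-stock-biomass table and an individual body-size table,
from which per-year sample moments are computed. Half of the analysis years
train the baselines; the second half is assessed. Size records are analyzed
as given — no length-weight conversion is applied, since the trait pipeline
only requires a size-valued trait, and any allometric conversion would be a
monotone reparameterization of it. The shipped fixture generator
(`make_survey_fixture()`) produces a "recovering" stock (post-split upward
shifts in SSB, mean size and SD size) and a mean-stationary
"not recovering" stock; both are synthetic stand-ins for survey extracts,
deterministic in their seed. The default seed ships with the verified
property that the stationary fixture never crosses the 2-sigma threshold in
its assessment window while the recovering fixture yields consecutive
signals in most size-containing metrics.

## Known limitations

* Single species: no predation kernels, no background resource dynamics, no
  community rearrangement after release; the overshoot and the noise
  filtering of a multispecies web are absent (see Calibration).
* The historic 1967-2010 fishing series is a stylized ramp, not the
  recorded one.
* Survey sampling error is not modelled in the simulator: the annual
  records are exact integrals of the size distribution, so the simulated
  false-positive rates are a best case.
* The number-weighted size moments are dominated by the smallest observable
  classes, which is what survey counts measure, but differs from
  biomass-weighted summaries used by stock assessments.

## A worked run

```{r example, eval = FALSE}
ens <- generate_ensemble(n_reps = 50, base_seed = 101)
analysis <- ews_analysis(ens)
summarize_ensemble(analysis, rule = "consecutive")
roc_curve(analysis, "AR(1) + SD size", "single")
training_length_sweep(ens, "AR(1) + SD size")
```
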