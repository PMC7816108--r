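---
title: "A 3-state Markov model for second-line pembrolizumab in advanced HCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A 3-state Markov model for second-line pembrolizumab in advanced HCC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceahcc)
```

## The decision problem

Advanced hepatocellular carcinoma (HCC) that has progressed on sorafenib
has few systemic options, and the anti–PD-1 antibody pembrolizumab showed
a modest survival benefit over placebo in its randomized second-line
trial (median overall survival 13.9 vs 10.6 months, hazard ratio about
0.78). `ceahcc` re-implements, as an open and testable R package, a
published US-payer cost-effectiveness evaluation of that comparison. The
question the model answers is the standard one in health technology
assessment: at pembrolizumab's list price, does the survival and
quality-of-life gain cost less than a willingness-to-pay (WTP) threshold
of \$150,000 per quality-adjusted life-year (QALY)?

## Model structure

The core is a cohort state-transition (Markov) model with three health
states — progression-free (PF), postprogression (PP), and death —
advanced in 3-week cycles (21 days; with 1 month defined as 365.25/12
days one cycle is 0.6899 months). The cohort enters 100% progression-free
at age 62. Per cycle starting at time $t$:

* the death probability applied to both alive states is
  $p_\text{death}(t) = \max\{1 - S_\text{OS}(t+\Delta)/S_\text{OS}(t),\;
  p_\text{bg}(t)\}$, where $S_\text{OS}$ is the arm's overall-survival
  law and $p_\text{bg}$ the life-table background mortality converted to
  the cycle length, $1-(1-q)^{\Delta/12}$;
* the progression probability is the progression-free exit probability in
  excess of death, $p_\text{prog}(t) = \max\{0,\;
  1 - S_\text{PFS}(t+\Delta)/S_\text{PFS}(t) - p_\text{death}(t)\}$, with
  the PFS curve clipped pointwise below the OS curve.

Taking the death hazard from the OS curve for *both* alive states makes
the trace's alive total reproduce the OS curve exactly (wherever the
disease hazard exceeds background), which is the property the published
description pins down; state-specific post-progression hazards are not
identifiable from the published marginals. A partitioned-survival mode
(PF occupancy read directly off the PFS curve, alive total off the OS
curve) is available behind `model_config(structure = "partitioned")` and
agrees with the Markov mode on the alive total by construction.

Background mortality enters as a *floor* (`max`) rather than a sum by
default. The published text says overall death "included" background
mortality, which is ambiguous; the floor avoids double counting (the OS
curve already contains deaths from any cause) while guaranteeing
mortality never falls below the life table. The alternative
independent-competing-risk combination is available via
`model_config(background_mode = "add")`. The choice is immaterial at this
horizon — the disease hazard dominates the life table throughout — and
matters only in the cure scenario and deep extrapolation.

Life-years, QALYs and state-occupancy costs are accrued with a
trapezoidal half-cycle correction (the average of start- and end-of-cycle
occupancy), discounted at 3% per year with the start-of-cycle discount
factor; one-time costs (adverse events, end-of-life) are not
half-cycle-corrected. The final model cycle is truncated at the horizon
so that a 3-year run accrues exactly three years — without truncation the
53rd 21-day cycle would overshoot the horizon by more than half a cycle.

## Survival inputs

Because no patient-level data are available, survival curves enter in one
of two ways.

**Calibration from printed statistics** (the reproduction path). The
pembrolizumab OS curve is the Weibull $S(t) = \exp(-(t/\sigma)^k)$
passing through the printed median (13.9 months) and the printed
30-month survival (25%); the closed form gives
$k = \ln(\ln 0.25/\ln 0.5)/\ln(30/13.9) \approx 0.901$ (a mildly
decreasing hazard). The placebo curve shares that shape and is anchored
at its own printed median (10.6 months), which reproduces the printed
hazard ratio of 0.78 to three decimals. PFS medians were not printed in
the source; the packaged configuration uses the trial's reported medians
of 3.0 (pembrolizumab) and 2.8 (placebo) months with a Weibull shape of
1.2 (rising hazard, typical of progression endpoints); both are marked
"assumed" in `base_case.yaml` and are overridable.

**Fitting to reconstructed pseudo-IPD** (the general path). Digitized
curve coordinates plus the number-at-risk table are inverted to
patient-level records by `reconstruct_ipd()`, and `fit_param_surv()` fits
exponential, Weibull, log-logistic or log-normal laws by right-censored
maximum likelihood (via `flexsurv`), with `aic_select()` choosing among
them by Akaike information criterion (ties broken toward fewer
parameters).

### KM inversion details

Within each interval between consecutive risk-table times, integer event
counts at the digitized reading times and a censoring count are solved so
that (i) the product-limit curve of the output tracks the input
coordinates and (ii) the at-risk counts match the risk table exactly at
every boundary. Three numerical choices matter:

* *Boundary attribution.* A reading that falls exactly on a risk-table
  time carries the survival drop accumulated during the interval that
  ends there, so its events are assigned to that interval (and placed
  just inside it). Grid-aligned digitizations otherwise smear one
  reading's worth of events into the next interval, where the at-risk
  constraint cannot absorb them.
* *Greedy integer events.* At each reading the integer event count is the
  one whose KM update lands closest to the digitized value, rather than a
  rounded real count; rounding errors then cannot accumulate.
* *Censor placement.* Censoring times start from an even layout across
  the interval, but the split of censors around each reading is adjusted
  (ties toward the even layout) when the even layout cannot reproduce the
  reading's drop factor — late in follow-up, where risk sets are small,
  the size of the risk set at an event visibly changes the step height.

All rules are deterministic, so reconstruction is reproducible
bit-for-bit. On noiseless synthetic digitizations (200 patients, 1-month
grid, 3-month risk intervals) the round-trip sup-norm error is below
0.005 and the at-risk counts match exactly; the test suite asserts the
0.02 bound. An optional total-event constraint rescales interval event
counts by largest-remainder rounding, at the cost of an approximate
at-risk match when the imposed total is inconsistent with the table.

## Economics

Per cycle, patients in PF below the 35-cycle (2-year) treatment cap
accrue drug (\$6,915 per cycle for pembrolizumab, \$0 for placebo) plus
administration (\$150) costs. Newly progressing patients trigger, with
the arm's treated fraction (41.7% / 47.4%), a postprogression therapy
stream (\$6,620 / \$5,963 per cycle) modeled as a fixed-duration annuity
discounted from the progression cycle. The duration was not printed in
the source; the default of 6 cycles (about 4.2 months) is in the range
reported by the second-line HCC trials the source drew on, and is
configurable. Utilities are 0.84 / 0.76 (PF, by arm) and 0.68 (PP, both
arms). Adverse-event profiles (one-time cost and QALY decrement per
episode) are supported in the schema but default to empty, and
end-of-life cost defaults to zero and equal across arms — the source's
supplementary tables carrying those values are not available, and its
sensitivity analysis does not rank them among the influential parameters.

`compare()` produces the incremental cost, life-years, QALYs, the ICERs
where well-defined, and a dominance classification otherwise;
`net_monetary_benefit()` is $\lambda\,\Delta\text{QALY} - \Delta C$.

## Sensitivity machinery

* **One-way (tornado):** each parameter to its range ends (printed
  confidence-interval-style ranges where available, ±20% otherwise),
  ICERs capped at \$2M/QALY for display as the incremental QALY collapses
  near hazard ratio 1.
* **Two-way:** an ICER grid over two ranges with a cost-effective region
  classification.
* **PSA:** joint independent draws — beta for utilities and fractions,
  gamma for costs (both by method of moments, reading the range as a 95%
  interval), log-normal for the OS hazard ratio (95% CI 0.61–1.00) —
  with one full model evaluation per draw and the acceptability curve
  CEAC($\lambda$) = fraction of draws with positive net monetary benefit.
  Out-of-domain draws are rejection-resampled and counted. No correlation
  structure is imposed; none is published.
* **Threshold:** bisection on the per-cycle price until the ICER is
  within \$0.001/QALY of the target (well inside the \$1 guarantee);
  since the cost side is affine in price at fixed curves, this matches
  the analytic inversion to under a cent.
* **Scenarios:** the 30-month cure (both arms switch to pure background
  mortality after the landmark, at the same calendar time from model
  start), the 400 mg q6w schedule, and 5-year/10-year/lifetime horizons
  (lifetime = to age 100).
* **Subgroups:** the placebo OS curve is held fixed and the pembrolizumab
  curve re-derived under proportional hazards with the shared Weibull
  shape from a subgroup hazard ratio.

A note on the q6w schedule: the reproduction models it as an equal drug
cost per unit time with halved administration events, as the schedule
implies. Because on-treatment occupancy declines within each 6-week
window, charging a double dose at the window's start front-loads cost
slightly, so in this implementation the schedule *raises* the ICER a few
percent rather than lowering it as the source reports; the source does
not state what drove its reduction (a per-milligram price difference
would), so this scenario is a structural illustration, not a reproduced
number.

## The synthetic-data generator

`simulate_ipd()` emulates a KEYNOTE-240-like arm: Weibull OS (medians
13.9/10.6 months, shape 0.901, implied HR ≈ 0.78), short Weibull PFS
(medians 3.0/2.8, shape 1.2), uniform accrual over 18 months (the actual
accrual pattern is unpublished) and a 30-month administrative cutoff,
interpreted so that the cutoff is the maximum follow-up. OS and PFS are
coupled *comonotonically*: one uniform rank per patient is pushed through
both inverse survival functions. This preserves both marginal laws
exactly — so the Kaplan-Meier estimate of a large simulated sample
converges to the generating law, which the tests assert at n = 50,000 —
and guarantees progression-free time ≤ survival time per patient whenever
the PFS law lies below the OS law pointwise, as in every shipped
configuration. (The simpler independent-draw-with-max coupling distorts
the OS marginal by up to ~0.07 early on, because the PFS law sits far
below the OS law here.) `digitize_curve()` and `make_risk_table()` then
emulate what a graph digitizer and a published risk row would yield,
including optional seeded Gaussian jitter with an isotonic repair.

What the generator does **not** emulate: informative or dropout
censoring (censoring is purely administrative), delayed separation or
crossing hazards typical of immunotherapy KM curves, response/RECIST
dynamics, adverse-event incidence, or any correlation between survival
and economic quantities. Passing round-trip and convergence tests on
these fixtures therefore demonstrates that the *pipeline* is correct and
stable, not that digitizing a real published figure would recover the
original trial data to the same accuracy.

## Fidelity of the reproduction, and a known limitation

The packaged configuration reproduces the published per-arm quantities
closely (discounted life expectancy within about 4% and 1% for the
pembrolizumab and placebo arms, per-arm QALYs similarly). The
*incremental* quantities — small differences of similar numbers — are
substantially more sensitive to the exact survival parameterization. The
printed calibration targets (two medians, one landmark, a shared shape)
pin both OS curves completely, and the curves they imply carry a larger
between-arm gap than the source's own fitted Weibulls (whose parameters
were only reported in an unavailable supplement): a placebo-scale Weibull
matching the published placebo life expectancy combined with the
published pembrolizumab life expectancy implies a pembrolizumab shape
near 1.05 with 30-month survival near 21%, not the 25% printed from the
trial data. The package follows the printed calibration rather than
tuning toward the published incrementals; the acceptance suite therefore
shows the incremental QALY, incremental life-years, threshold-price and
acceptability-at-threshold checks outside their bands while the per-arm,
cure-scenario, horizon-ordering and structural-property checks pass.
Every number in that comparison is computed at run time by
`reproduce_analysis()` and `scripts/acceptance.R`; none is hard-coded.

## Problem sizes and defaults

Deterministic analyses run a 53-cycle trace per arm and complete in
milliseconds. The packaged PSA default is 10,000 Monte Carlo draws
(about half a minute); the test suite uses 2,000 draws, and round-trip
fixtures use 200-patient samples with convergence checks at 50,000. Seeds
are explicit arguments everywhere randomness enters and are recorded in
the run manifest.
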