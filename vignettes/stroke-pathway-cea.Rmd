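---
title: "Methods: before/after cost-effectiveness modelling of centralized acute stroke care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: before/after cost-effectiveness modelling of centralized acute stroke care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The problem

Centralizing acute stroke care — routing every suspected stroke to a small
number of high-volume hyper-acute stroke units (HASUs) instead of thirty
local hospitals — cannot be evaluated with a randomized trial: the
intervention is a city-wide service reconfiguration. The alternative is a
before/after comparison built on patient-level register data, with two
threats handled explicitly: (i) secular national improvement in stroke
outcomes over the same years, removed by trend adjustments to the "before"
arm, and (ii) parameter uncertainty, propagated by probabilistic
sensitivity analysis. `strokecea` implements that full design as a tested
pipeline, with a synthetic register generator standing in for confidential
registry data so every stage can be validated end to end.

## Model structure

**Short-run model (admission to 90 days, daily cycles).** Health states
are ward types and discharge locations. The "before" pathway admits to an
acute stroke unit (ASU), stroke-rehabilitation ward, medical ward,
surgical ward or ICU; the "after" pathway admits predominantly to a HASU
that feeds a stroke unit (SU). Discharge states are home, home with early
supported discharge (ESD), and nursing home; death is absorbing. Each
state's row of the daily transition matrix is assembled from fitted
hazards; the initial distribution is the observed first-admission-ward
mixture.

**Long-run model (90 days to 10 years, 90-day cycles, 40 cycles).**
Survivors at day 90 move to a residence/disability space: three home
states defined by Barthel-index bands (independent 15–20, moderate 10–14,
dependent 0–9), institutional care, and death. Patients at home are split
across the bands by the register's 90-day Barthel mixture; nursing-home
patients enter institutional care; patients still in hospital go to
institutional care by default (a scenario sends them home instead).

## Survival machinery

All parametric fits use the proportional-hazards Weibull convention

$$S(t \mid x) = \exp\{-(t/\lambda)^k e^{x'\beta}\},$$

with shape $k$ (dimensionless), scale $\lambda$ (days), and covariates on
the log-hazard scale; this is stated wherever $\lambda$ appears because
other conventions exist. Fits are maximum likelihood via `survreg`, with
the covariance of $(\log\lambda, \log k, \beta)$ obtained from the
observed information by the delta method. Kaplan–Meier estimation uses
Greenwood variance with linear 95% bounds clipped to $[0,1]$; at tied
times events precede censorings. Cox models use Breslow tie handling —
simplest to verify against a written-out partial likelihood, at the cost
of slight attenuation under heavy ties. Separate death-time models are fit
per period so the two arms may have different shapes.

Two conventions matter downstream:

* *Integer-day grid.* Day 0 is the admission day; a death during day $d$
  is recorded as day $d$ (the floor of the continuous death time), so
  "alive at day 90" corresponds to a continuous death time of at least 91.
  The generator's calibration solver anchors survival at day 91 for this
  reason. Deaths recorded on day 0 are imputed as 0.5 days in parametric
  fits, the natural half-day imputation on a daily grid.
* *Population-average hazard.* The cohort model propagates an aggregate
  cohort, so its daily death probabilities come from the *marginal*
  (covariate-free) per-period Weibull. An age-adjusted fit (age centred at
  the register mean) is computed alongside for reporting; using it to
  drive the cohort would require an age-stratified trace, which is out of
  scope.

Daily transition probabilities are survival ratios,
$p(d) = 1 - S(d+1)/S(d)$, computed internally via cumulative-hazard
increments $1 - e^{-(\Lambda(d+1) - \Lambda(d))}$, which is algebraically
identical but immune to floating-point underflow of $S$ at late days under
extreme parameter draws.

## Competing risks within a day

Ward exit and death compete within each daily cycle. Each marginal
probability $p_i$ is converted to a rate $r_i = -\ln(1-p_i)$; the total
exit probability is $1 - e^{-\sum r_i}$, allocated proportionally to the
rates. This composition is order-independent and exact when hazards are
constant within the day. It slightly understates deaths on days with very
fast ward turnover (the interaction term $\approx r_d r_e/2$); across the
default conditions this biases 90-day model survival upward by a few
tenths of a percentage point relative to the model-free Kaplan–Meier
estimate, well inside the sampling tolerance the tests allow. No
half-cycle correction is applied in the short-run model: with daily cycles
it would change accruals by less than one part in a thousand.

## National-trend adjustments ("before" arm only)

* **30-day mortality.** National audit data show cumulative 30-day stroke
  mortality outside the study city fell by 2.4 percentage points (20.7% to
  18.3%) between the two periods. The adjustment rescales every into-death
  entry of the daily matrices for days 0–29 by a single factor, found by
  bisection so cumulative death occupancy at cycle 30 falls by exactly the
  requested points; freed mass returns to each source state's diagonal and
  hazards from day 30 onward are untouched. Rescaling preserves the hazard
  *shape*; an alternative "subtract" method removes a constant amount per
  day instead (flattening the shape). Both are implemented because the
  historical analysis did not state which it used; rescaling is the
  default.
* **Stroke-unit length of stay.** Mean stroke-unit stay fell nationally by
  5.0 days (23.1 to 18.1). The adjustment rescales the exit-time Weibull
  scale of the designated ward so the implied mean $\lambda\Gamma(1+1/k)$
  drops by exactly the requested days, then rebuilds the schedule. By
  default it targets the stroke-rehabilitation ward — in the "before"
  pathway the acute (ASU) stay is short (median 4 days) and the ongoing
  stroke-unit stay that national audits measure is the rehabilitation
  stay. The target ward set is configurable. The length-of-stay adjustment
  is applied before the mortality adjustment so the mortality target is
  hit on the final schedule.

## The synthetic register generator

The generator emulates the *structure* the analysis needs, under the
observed study conditions: per-period cohort sizes (307 / 3,156), age
(71.0 ± 15.2 / 72.8 ± 14.9), sex (51% male), stroke type (85% / 88%
ischemic), thrombolysis (5% / 13%, ischemic patients only), admission
Barthel (9.3 ± 7.6 / 10.7 ± 7.8), first-ward mixtures from the observed
first-admission counts, and imaging/intervention rates. Death times follow
a proportional-hazards Weibull with age acting at log-hazard 0.03 per year
around age 72 — a moderate, realistic elderly-mortality gradient. Given
the shape, the scale is solved at configuration time so that *marginal*
(age-averaged) 90-day survival equals the observed anchors: 81.5% before,
88.7% after. Shapes of 0.85 (before) and 0.70 (after) encode the
front-loaded early stroke mortality hazard; with the survival anchors
fixed, this choice also places the pooled age-adjusted period hazard ratio
near its observed value of about 0.55 (the calibration was done once, by
simulation, against those published anchors, and the defaults frozen).

Ward pathways are built episode by episode: a latent length of stay per
ward (Weibull) competes with the latent death time; the earlier fires,
ties resolved death-first. Exits alive draw a destination from the ward's
mixture; discharge states are terminal residences occupied until death or
censoring, so episode records tile the whole follow-up and the last exit
day equals the death day whenever the patient dies under follow-up.
Destination mixtures are assumptions chosen to reproduce the observed
discharge pattern (roughly 60%/70% at home and 5%/1% in nursing homes at
90 days before/after; the after-period acute units essentially empty by
day 90). The 90-day Barthel is the admission score plus a truncated-normal
improvement (mean 3 before, 4 after, SD 3, truncated at zero), clipped to
[0, 20] — the improvement parameters are free configuration, since only
admission-time Barthel summaries are published.

What the generator does **not** emulate: record-linkage artefacts, missing
data, stroke recurrence within 90 days, and any dependence between age,
severity and ward pathway (they are generated independently unless
configured otherwise). Passing tests therefore demonstrate the pipeline's
correctness and calibration under these idealized conditions, not the
behaviour of real registry data.

## Economics

Utilities derive from the Barthel index through an affine map
$u = 0.05\,\mathrm{BI} - 0.235$, clipped to $[-0.235, 1]$. This is a
calibration stand-in, chosen to pass exactly through the two published
(mean Barthel, mean utility) anchor pairs (9.3, 0.23) and (10.7, 0.30); it
is *not* the published Barthel→EQ-5D algorithm, whose coefficients are not
public. A monotone lookup table over the 21 Barthel levels can be supplied
instead.

Costs are 2010/11 UK£ from an NHS + personal-social-services perspective.
Ward and residence states carry per-day (short run) or per-90-day-cycle
(long run) costs; ambulance conveyance, imaging, carotid stenting,
neurosurgery and thrombolysis are one-off expected-value costs at
admission (probability × unit cost × cohort), using the observed
per-period event rates. All default unit costs and the long-run transition
matrix are documented assumptions (the original unit-cost and long-run
transition tables are unpublished); consequently **absolute** cost and
long-horizon QALY magnitudes depend on this configuration, while the
direction of the comparison and the survival quantities are driven by the
calibrated survival models. Under the `NHS-only` perspective the
social-care states (home care, nursing home, institutional care) carry
zero residence cost, which can only lower an arm's total. Discounting is
3.5% per year, $(1.035)^{-d/365.25}$, applied at mid-cycle days in the
10-year horizon (90-day cycles are long enough for within-cycle timing to
matter); the 90-day report is undiscounted.

The dominance rule follows the standard reporting convention: the new
model is *dominant* when it costs less and has fewer deaths or more QALYs,
*dominated* in the mirror case, and otherwise ICERs (cost per death
averted, cost per QALY gained) are reported.

## Probabilistic sensitivity analysis

Parameter groups and distributions (all configurable, any group freezable):

| group | distribution | anchored to |
|---|---|---|
| survival shape/scale | bivariate normal on the log scale | fit covariance |
| destination & first-ward mixtures | Dirichlet | observed counts |
| one-off event probabilities | beta | rate × period sample size |
| unit costs | gamma, CV 0.2 | point estimate |
| long-run transition rows | Dirichlet, effective n = 200 | stand-in matrix |

Each draw rebuilds both arms' schedules (including the trend adjustments),
runs both Markov models, and records the cost/death/QALY increments at
both horizons; confidence intervals are empirical 2.5/97.5 percentiles,
and the acceptability curve reports the fraction of draws with positive
net monetary benefit $\lambda\,\Delta\mathrm{QALY} - \Delta\mathrm{Cost}$
on a £0–50,000 grid covering the £20,000–£30,000 decision range.
Parameters are drawn independently across groups (within-fit correlation
enters through the fit covariance); joint sampling across transition rows
is not implemented. Individual draw failures are excluded and counted;
more than 1% aborts the run.

## Numerical choices

* Mortality-adjustment bisection: 70 iterations on the scaling factor,
  hitting the 30-day cumulative target to ~1e-12 of the cohort.
* Degenerate fits fail loudly: no events, all events at a single instant,
  constant Cox covariates and suspected separation all raise explicit
  errors rather than returning defaults. Wards observed too rarely to
  support a Weibull fit (fewer than two exits) fall back to a regularized
  exponential exit model with a weakly-informative rate.
* Schedules are validated (non-negativity, row sums within 1e-9, death
  row absorbing) before propagation; cohort conservation (1e-6) and
  monotone death occupancy are asserted every cycle.
* Reproducibility: a single master seed fans out to fixed per-module
  sub-streams (generator arms, PSA), so identical configuration and seed
  give byte-identical outputs.

## Problem sizes used in validation

The test suite exercises the generator at up to 10,000 patients for
marginal-calibration checks, recovers generating Weibull parameters at
n = 5,000 within three standard errors, validates the cohort trace against
a 100,000-walker microsimulation, and checks the pooled age-adjusted
hazard ratio across 50 replicate register pairs at the study sample sizes.
The acceptance script runs the full pipeline at the study conditions with
a 2,000-draw sensitivity analysis — enough for Monte-Carlo error on CEAC
probabilities of under one percentage point; the package default for
production use is 10,000 draws.

## Known limitations

* The cohort model is aggregate: no age-stratified traces, frailty, or
  time-in-state (duration) dependence — ward-exit hazards depend on days
  since admission, not days on the ward.
* Long-run transitions, unit costs and the utility map are assumption
  defaults; conclusions about absolute cost magnitudes should only be
  drawn after replacing them with setting-specific values.
* Stroke recurrence is not an explicit event; it is absorbed into the
  long-run state-drift probabilities.
* The before/after design itself cannot exclude residual confounding
  beyond the modelled national trends; the scenario battery probes the
  main assumptions but not that design limitation.
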