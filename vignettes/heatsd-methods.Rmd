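---
title: "A stock-flow model of heat-wave mortality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stock-flow model of heat-wave mortality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatsd)
```

## The model

`heatsd` implements a daily system-dynamics model of how an extreme heat
wave stresses a city's public-health system. The single stock is the
affected population AP: residents whose health has been compromised by heat
to the point of needing care. Three flows act on it, all in persons/day,
integrated by explicit (forward) Euler with a one-day step:

* **Affected-people inflow (APF).** Heat morbidity rises once the daily
  maximum temperature exceeds 36.6 degrees C. We model the inflow per ten
  million of the exposed population as a baseline rate `r_base` plus a
  linear excess `beta_morb * max(0, tmax - 36.6)`. The exposed population
  weights the elderly: `total * (1 + vuln_over65 * share_over65)`, because
  age structure acts on exposure rather than on treatment capacity.
* **Treated-people outflow (TPF).** `TPF = AP * AF`, where the adaptation
  factor AF is the daily fraction of affected people the city manages to
  treat and recover.
* **Death outflow.** `deaths = AP * mu * CF`, a baseline case-fatality
  fraction `mu` amplified by the climate severity factor
  `CF = MA(tmax) * HDAF(hot_days)`. The stock-flow balance as a pure
  in/out pair would never emit mortality, so the death flow is a third,
  explicit outflow; it is the quantity the model exists to produce. The
  mortality threshold of 37.6 degrees C enters through the convention that
  MA equals 1 below that temperature.

When the two outflows together would exceed the stock plus the day's
inflow, both are scaled by the same factor so that mass balance and the
treated:death ratio are preserved exactly. Mass balance —
`initial AP + sum(APF) = final AP + sum(TPF) + sum(deaths)` — holds to
floating-point tolerance at every step and is enforced by a property test.

**Table functions.** MA (maximum-temperature amplification) and HDAF
(hot-day amplification) are piecewise-linear table functions: ordered
breakpoints, linear interpolation, clamped (constant) extrapolation outside
the breakpoint range. Clamping rather than linear extrapolation prevents
negative or explosive factors when a scenario pushes temperatures past the
calibrated range. HDAF takes the *consecutive hot-day count* as input — the
number of days above 35 degrees C ending today, reset to zero by a single
cool day — so prolonged waves amplify mortality beyond what the day's
temperature alone explains.

**Adaptation.** `AF = af0 * EC * HF * GF`. The economic factor EC
(air-conditioning usage, income), health factor HF (medical staff, beds,
hospitals) and governance factor GF (minimum living allowance, insurance
coverage) are weighted power laws (Cobb-Douglas) of indicator/reference
ratios. This composition was a genuinely open design choice — which
indicators drive each factor is established, how they combine within a
factor is not — and the power law was chosen because it is dimensionless, equals
1 at the reference city, is monotone in every indicator, and has one
exponent per indicator for calibration. `af0` is the calibrated baseline
treated fraction of the reference city; component factors are clamped to
`[1e-3, 10]` and AF is capped (default 0.95/day) so it remains a valid
fraction for any admissible profile. A consequence guaranteed by
construction: adding beds or raising the allowance can never increase
simulated deaths.

## Heat-wave definition

Episodes follow the China Meteorological Administration consecutive-day
rules: a run of days with maximum temperature *strictly* exceeding 35
degrees C qualifies as a strong heat wave at 5 days (or 2 consecutive days
above 38), and as extreme at 8 days (or 3 consecutive days above 38).
"Exceeding" is read literally: a day at exactly 35.0 is not hot, and the
thresholds are configurable. Episode boundaries are maximal hot runs; one
cool day ends an episode and resets the hot-day counter. A run satisfying
both rules is labelled with the more severe class. All indices in the R
API are 1-based; reports count "day N" from the first day of the episode.

## Scenarios

Four scenario kinds transform the baseline inputs declaratively:

| kind | transformation | default |
|------|----------------|---------|
| `baseline` | none | — |
| `temp_offset` | add `delta_temp` to every day's temperatures | — |
| `bed_readiness` | beds × (1 + `bed_fraction`) from the warning day | +20% |
| `allowance_increase` | allowance × `allowance_multiplier` from the warning day | ×1.2 |

The warning day defaults to the first simulated day: the bed measure is
modelled as active for the whole episode, matching a warning received in
advance. Comparisons are made on *total* daily deaths — the
heat-attributable flow plus a constant background equal to the city's
cool-day mortality (114 deaths per ten million per day) — since observed
death series are totals.

## Synthetic data

No station records or mortality microdata ship with the package; the
generators produce stylized stand-ins with the statistical structure the
analysis needs.

* `gen_heatwave_series()` builds a rise-plateau-fall temperature profile
  with seeded jitter of ±0.3 degrees C that is clamped so no day crosses
  the 35-degree threshold: episode durations are exact by construction.
  The `hw2003` preset is a 19-day extreme episode (half-sine arc, peak
  40.0); `hw2013` is a 15-day episode with a *twin-peak* plateau — primary
  maximum 40.5 degrees on episode day 8, a dip, and a weaker secondary
  maximum near day 12. The July 2013 event arrived in two hot spells, and
  the within-episode structure of the mitigation results (largest
  reductions on days 7-8, with a secondary response around day 12) is a
  consequence of that double peak; a single-bump profile cannot reproduce
  it, because percentage-reduction curves of treatment-scaling scenarios
  are nearly proportional across days. The 40.5-degree peak itself is a
  documented free choice (the event's daily values are not published in a
  reusable form), set above both the 36.6 and 37.6 thresholds.
* `gen_city_profile()` returns fixed indicator profiles on the published
  order of magnitude for 2013 (24.1 million residents, 15% over 65,
  allowance 790/month) and 2003. They are synthetic, not yearbook
  extracts.
* `gen_baseline_mortality()` draws daily deaths from a Poisson law with
  mean 114 per ten million on cool days and 124 above 35 degrees C — the
  observed step in summer daily mortality across the 35-degree threshold.
* `gen_observed_deaths()` forward-simulates total daily deaths under known
  parameters and applies Poisson observation noise; this is the ground
  truth for the parameter-recovery tests.

What passing tests on these fixtures shows — and does not show. The suite
demonstrates internal correctness (mass balance, oracle equivalence of the
integrator, monotonicity of the adaptation machinery), statistical sanity
of the generators, and that the shipped calibration reproduces the headline
scenario statistics on the packaged fixtures. It does not validate the
model against real station or CDC data, which are not redistributable;
absolute death-toll levels in particular are uncalibrated (see below).

## Calibration

`calibrate_model()` minimises the squared error (or RMSE) between
simulated and observed total daily deaths over a user-declared free
parameter set with finite box bounds. The optimizer is bounded
Nelder-Mead with multi-start — parameters map to the unconstrained scale
by a logistic transform of their bounds; the box midpoint plus seeded
uniform draws give the starts; Brent's method replaces Nelder-Mead in one
dimension. A derivative-free method was chosen because the objective is
cheap but non-smooth (table-function kinks, factor clamps, the outflow
cap). The recovery properties enforced by tests: on forward-simulated
data from a 28-day series with an 18-day episode, the headline free set
{`beta_morb`, `mu`, `af0`} is recovered within 1% without noise and
within 10% under Poisson noise.

`validate_fit()` reports RMSE, the relative peak-value error and the peak
lag in days (`argmax(sim) - argmax(obs)`, ties to the earliest day) — the
criteria for judging whether a calibrated model reproduces the peaking
process of a held-out episode, such as the 2003 wave, to within a one-day
lag.

### The shipped default calibration

`default_params()` loads the committed parameter file. Because no real
death series is available, its free parameters were fitted (by the same
bounded multi-start Nelder-Mead machinery, outside the package) so that
the scenario experiments on the packaged `hw2013` fixture reproduce the
published headline statistics: daily-death reductions of 15.8%/19.5% on
episode days 7/8 under 20% bed readiness, 21.9%/17.7% on days 8/12 under
the 20% allowance increase, and mean increases of 11%/23% under +1/+2
degree offsets. Structure fixed in advance of that fit: MA breakpoints at
(35, 37.6, 38.8, 40.0, 40.4, 42.6) with MA = 1 below 37.6 and monotone
heights; HDAF breakpoints at hot-day counts (0, 7, 8, 12, 20) with
monotone heights, the 7/8 pair letting amplification accelerate once a
wave persists beyond a week; weights for indicators never exercised by the
scenarios held at documented constants.

One ordering caveat. Both mitigation measures act through the same
mechanism — a scalar multiplier on the adaptation factor — so their
percentage-reduction curves can differ across days only through how decay
compounding saturates, and that moves both scenarios' day-12 : day-7
ratios in the same direction. The bed measure's two largest reductions
fall on days 7 and 8, as published, and the allowance values on days 8
and 12 are at their published levels; but the model cannot simultaneously
rank the allowance's day 12 above its day 7, which ends up marginally
higher (~18%). Reproducing the published allowance ordering exactly would
require a scenario asymmetry (for example a treatment delay specific to
one measure) that the model structure does not contain.

Two properties of this calibration deserve emphasis. First, the scenario
percentages pin down only *relative* behaviour; the absolute scale of the
simulated death tolls is not identified by them and is larger than the
historical event's, because reproducing a ~20% reduction in total deaths
from a 20% capacity increase requires the heat-attributable share of
mortality to be large. Users fitting real data should calibrate against
their own observed series rather than rely on the shipped absolute levels.
Second, the regime is stock-dominated: a sizeable initially-affected
population drains over the episode, which is what makes the percentage
reductions grow day by day early in the wave.

## Numerical choices and degenerate inputs

* Integration is forward Euler at exactly one day; no sub-stepping. All
  state stays in double precision; death counts are rounded (half-up) only
  at reporting time.
* Proportional outflow scaling on stock exhaustion preserves the
  treated:death ratio implied by the flow definitions.
* Table evaluation at a breakpoint returns its height exactly; abscissae
  must be strictly increasing.
* Zero-valued indicators (for example `staff = 0`) are floored at 1e-3 of
  the reference ratio rather than annihilating a factor.
* The argmax tie-break (earliest day) matters for the peak-lag metric on
  flat series and is fixed by test.
* Per-day monotonicity in temperature — warmer never means fewer deaths on
  any single day — holds while outflows stay strictly inside the stock;
  once the exhaustion clamp engages, extra early deaths deplete the stock
  and can lower a later day's toll. The property tests assert the
  interior-regime version.

## Limitations

* No humidity or apparent-temperature exposure; maximum temperature and
  episode duration are the only climate drivers.
* No distributed-lag exposure structure and no mortality-displacement
  (harvesting) adjustment.
* One city, one profile; no spatial heterogeneity.
* The exposure-response slopes published for the 36.6/37.6-degree
  thresholds are not available; the linear-excess form with a calibrated
  slope is the simplest monotone stand-in.
* Whether climate severity should also modulate the inflow, rather than
  only the death flow, is a modelling judgement call; the config exposes
  `cf_on_apf` as an off-by-default switch for sensitivity analysis only.
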