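---
title: "Thermal-time phenology models: methods and design notes"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modeling problem

Grapevine budburst (BBCH 09) and flowering (BBCH 61) dates are driven
primarily by temperature. `vitipheno` implements the classical
forcing-accumulation framework: development proceeds at a daily rate
`Rf(x_t)` that depends only on the daily mean air temperature `x_t`, the
rate is accumulated from a start day `t0`, and the phenophase is predicted
on the first day the running total reaches a critical value `F*`:

    D = min { d : sum_{t = t0}^{d} Rf(x_t) >= F* }

The start day is included in the sum, and the predicted day is reported as
a whole day with no sub-daily interpolation of the crossing — event dates
are observed at day resolution, so finer output would be spurious
precision. Day indices anchor 1 January of the event year at 1; days of
the previous autumn are 0, -1, ... (1 September is -121), so start days
fitted into the previous year remain ordinary integers. Calendar
arithmetic, not a fixed 365-day year, maps dates to indices.

Three rate formulations are provided:

* **GDD** (`rf_gdd`): `max(0, x - Tb)` degree-days above a base
  temperature `Tb`. Three parameters (`t0`, `Tb`, `F*`).
* **GDD triangular** (`rf_triangular`): a piecewise-linear response over
  cardinal temperatures `Tmin < Topt < Tmax`, rising from 0 at `Tmin` to 1
  at `Topt` and falling back to 0 at `Tmax`. The zero branches use
  closed comparisons (`x <= Tmin`, `x >= Tmax`), so the rate is exactly 0
  at the outer cardinal points and exactly 1 at `Topt`.
* **UniFORC** (`rf_uniforc`): the sigmoid `1 / (1 + exp(d (x - e)))` with
  sharpness `d < 0` and mid-response temperature `e > 0`, and a hard zero
  below 0 degC. The sub-zero cutoff is part of the model definition as
  published for this model family and is implemented as printed, although
  it makes the rate discontinuous at 0 degC when `e` is small.

All three rates are non-negative; the triangular and UniFORC rates are
bounded by 1, making their `F*` a dimensionless forcing total rather than
degree-days. `x_t` is always the daily *mean* temperature; daily minima
and maxima are carried for data validation and synthetic realism only.

# Estimation

## Loss and the profiled forcing total

The fitting criterion is the residual sum of squares (SSres, days
squared) between observed and predicted event days. Minimizing SSres
simultaneously maximizes model efficiency

    EFF = 1 - SSres / SStot,  SStot = sum (obs_i - mean(obs))^2

and minimizes RMSE = sqrt(SSres / n), so the optimizer's criterion and
the reported selection metrics cannot disagree. Variety-years whose event
is never reached under a candidate parameter set are predicted at the
last day of their temperature series — a large but finite penalty that
keeps the search surface defined everywhere.

`F*` is not searched numerically. Given the start day and thresholds,
the predicted day for a year is a step function of `F*` whose breakpoints
are the year's cumulative forcing values; `estimate_fstar()` profiles
`F*` out as the mean cumulative forcing at the observed event days. One
refinement matters: when an interval of `F*` values reproduces *every*
observed day exactly (the maximum pre-observation forcing across years is
below the minimum observed-day forcing), and the mean falls outside that
interval, the estimate snaps to the interval's upper end. Without the
snap, the mean of the overshooting crossings would sit above some years'
observed-day forcing and shift their prediction one day late even on
noise-free data; with it, data generated by any parameter set inside the
search space refit with SSres = 0. Years with zero forcing accumulated by
the observed day carry no information about `F*` and are excluded (with a
warning in the user-facing function); if every year is excluded the
estimate is undefined and the objective falls back to the no-event
penalty.

## Metropolis simulated annealing

The threshold parameters are estimated by Metropolis simulated annealing
with geometric cooling (`T <- 0.95 T`), 200 proposals per temperature
level and an initial temperature calibrated from a short random walk so
that roughly 80% of initial uphill moves are accepted. Proposals change
one parameter at a time: integer parameters (the start day) move by 1-3
grid steps, continuous ones by a Gaussian step of sd 1 unit (1 degC for
temperatures), with reflection at the bounds; triangular proposals that
violate the cardinal ordering are rejected. The search stops after 60
temperature levels, after 10 levels without improvement, or immediately
at zero loss, and a deterministic coordinate-descent polish (at most 400
evaluations, step sizes shrinking from 4 to 0.01 units) refines the best
point. All of this is configurable through `sa_schedule()`; the defaults
are conventional Metropolis settings, not values with scientific content.

Two guards address a structural feature of this objective: parameter sets
under which *no* year accumulates forcing by its observed day (start day
after the events, or thresholds above the spring temperatures) form a
perfectly flat plateau of the penalty loss on which a Metropolis walk can
wander indefinitely. The start-day search bound is therefore clamped to
one day before the earliest observed event — accumulation that starts
after an observed event can never predict it — and the initial point is
resampled (up to 50 times) until the event is reachable.

Each fit runs 10 independent restarts from seeded starting points; the
root seed derives per-start seeds, so a fit is reproducible bit-for-bit
given its seed. The reported per-parameter (max; min) ranges span all
restarts whose final loss is within 5% of the best — a reproducible
operationalization of the spread that multi-start estimation produces.
Equal-loss ties are broken deterministically: smallest base/optimum
temperature, then earliest start day, then the remaining parameters.

## Default search space

| parameter | bounds | step |
|---|---|---|
| `t0` | 1..150 (January window) or -121..150 (September window) | 1 day |
| `Tb` | 0..30 degC | continuous |
| `Tmin` / `Topt` / `Tmax` | 0..15 / 5..30 / 15..50 degC | continuous |
| `d` | -40..-0.01 | continuous |
| `e` | 5..25 degC | continuous |

The lower start-day bound is 1 September of the previous year, the first
day the meteorology covers; published fits for this system lie inside
these bounds.

# The multistep workflow

`run_multistep()` chains the full procedure for one phenophase:

1. **Window comparison** — each variety is fitted with accumulation
   allowed from the previous 1 September and again restricted to start no
   earlier than 1 January; the window with the higher mean efficiency is
   retained, ties going to January (the simpler window). A coarser search
   (3 restarts) is enough for this binary decision.
2. **Per-variety calibration** — every requested model type is calibrated
   independently per variety. When several types are requested, one is
   selected by efficiency with a simplicity preference: the simplest
   model within 0.01 EFF of the best wins (GDD, 3 parameters, before
   UniFORC, 4, before triangular, 5). Significance testing and
   information criteria are deliberately out of scope — selection uses
   efficiency, error and parsimony only.
3. **External validation** — each variety's fitted model is applied with
   *frozen* parameters to every other variety, filling a donor x
   recipient grid of EFF/RMSE whose diagonal is, by construction, the
   estimation fit (the same prediction code path is used for both, so
   the identity is exact). The donor with the highest mean off-diagonal
   efficiency is flagged as the recommended transfer model.
4. **Global model** — a single parameter set is fitted on the pooled
   observations of all varieties (48 observations in the default
   12-season x 4-variety design).

Reported alongside the fits: difference-class frequencies — the
percentage of absolute errors in [0, 3], (3, 6] and (6, inf) days, with
boundary values in the lower class so the bins are disjoint and
exhaustive — and a linear regression through the origin of predicted on
observed dates. A slope `b0` near 1 indicates absence of systematic
bias; its 95% confidence interval uses the zero-intercept model's
residual variance on n - 1 degrees of freedom (a slope CI, not a
prediction band — the displayed-band convention varies across the
literature, and the slope CI is the choice made here).

# The synthetic-data generator

Published vineyard campaigns of this design are rarely shared, so the
package carries a generator that emulates their statistical structure:

* **Temperatures**: a sinusoidal seasonal cycle (annual mean 13.5 degC,
  half-amplitude 7 degC, minimum near 15 January — a temperate NW-Iberian
  wine-growing site) plus AR(1) daily anomalies (marginal sd 2.5 degC,
  lag-1 autocorrelation 0.75) and a per-year shift of the annual mean
  (sd 1.0 degC). Daily minima/maxima sit a diurnal half-range (5.5 degC)
  below/above the mean. Each series covers 1 September of the previous
  year through 31 August.
* **Events**: four varieties with GDD generating parameters seeded from
  published per-variety fits for this region (budburst start days 49-79,
  base temperatures 5-10 degC; flowering start days 27-72, base
  temperatures 6-7 degC), chosen so default campaigns land budburst
  around day-of-year 90-100 and flowering around 145-160.
* **Observation error**: rounded Gaussian noise (default sd 2 days) added
  to the *date*, mirroring field-visit uncertainty, optionally followed
  by snapping forward to the next visit day for cadences of 3-7 days.
  Noise on the date, not on the temperatures, keeps the generating model
  exactly recoverable at zero noise — the round-trip identity the test
  suite leans on.

Two generator choices deserve their "why". The per-year mean shift of
1.0 degC matches the year-to-year variability of spring mean temperatures
at sites like this; without it the inter-annual spread of event dates
collapses to a couple of days and every efficiency becomes meaningless
(SStot near zero). The AR(1) anomaly structure is not cosmetic either:
with white-noise days, multi-day warm spells and cold snaps vanish, and
the data then barely distinguish a low base temperature with a long
accumulation window from a high base temperature with a short one — the
SSres-optimal fit drifts to late starts and high thresholds, which an
exhaustive grid search confirms is a property of the surface, not of the
optimizer. Realistic anomaly persistence (daily sd 2-3 degC, lag-1
0.7-0.8) restores base-temperature identifiability. White noise remains
available (`ar1 = 0`).

What the generator does *not* emulate: weather-generator realism
(precipitation coupling, skewed anomaly distributions, trends), chilling
/ dormancy dynamics, photoperiod, management effects, and observer error
that correlates across varieties. Passing tests on synthetic data
therefore show that the estimation machinery recovers the assumed model
class under realistic noise — not that the GDD family is an adequate
description of any particular vineyard.

# Numerical choices and degenerate inputs

* Missing temperature days are a hard error in the readers; silent gap
  filling would bias accumulation totals.
* Efficiency is an error, not NaN, when observations have zero variance
  or n < 2; hugely negative efficiencies for bad parameter sets pass
  through unclamped.
* `rmse >= mad` is *not* asserted anywhere: it holds with equality for
  constant-magnitude residuals and can go either way otherwise.
* Event-day ties (several days reaching `F*` through a zero-rate
  stretch) resolve to the first crossing day.
* The no-event signal from `predict_event()` is a value
  (`reached = FALSE`), distinct from errors for malformed input.

# Problem sizes

The shipped tests calibrate on the default 12-season design: single
fits use 10 restarts; the optimizer-vs-grid and noisy-recovery checks
use 20 seeded replicates; the full workflow runs both phenophases with
default settings. `scripts/acceptance.R` regenerates the default
campaign and reruns the complete multistep workflow for both phenophases
from a single seed.

# Known limitations

* Chilling/dormancy-release and combined chilling-forcing models are out
  of scope; the forcing-only family can misattribute autumn/winter
  signal, which is exactly why the window comparison step exists.
* `F*` profiling assumes the observed day is a noisy version of a true
  crossing; under heavy-tailed observation error a robust profile (e.g.
  median) would be preferable.
* Multi-start ranges are a reproducibility diagnostic, not a confidence
  region; no uncertainty quantification beyond them is attempted.
* The annealer's schedule defaults are tuned for the shipped problem
  sizes (tens of years, single site); much longer series may need more
  temperature levels.
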