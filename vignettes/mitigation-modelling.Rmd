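---
title: "Modelling runoff and erosion mitigation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling runoff and erosion mitigation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnmuss)
library(dplyr)
```

`cnmuss` quantifies how in-field mitigation measures — micro-dams
("furrow diking": small earthen dams between crop ridges) and
conservation tillage by subsoiling — reduce surface runoff, soil
erosion, and ultimately pesticide concentrations in an edge-of-field
stream. This vignette explains the models, the conventions, and the
choices made where the design was genuinely open. It states no result
that the package's tests and acceptance script do not themselves
compute.

## The curve-number runoff model

Daily (or event) runoff is related to precipitation by the USDA-SCS
curve-number method. A curve number `CN` (dimensionless, at most 100)
maps to a potential maximum retention `S = 25400/CN − 254` mm; a fixed
fraction of `S` — the initial abstraction `Ia = ia_ratio · S` —
infiltrates before any Hortonian runoff starts, and thereafter

$$Q = \frac{(P - I_a)^2}{P - I_a + S}.$$

`ia_ratio` defaults to the standard SCS value 0.2 everywhere but is an
explicit argument of every function that uses it: field studies
sometimes prefer 0.05, and exposing the ratio keeps the event-wise
inversion honest about this assumption. For `ia_ratio = 0.2` the
inversion of a measured `(P, Q)` pair is closed-form
(`S = 5(P + 2Q − \sqrt{4Q^2 + 5PQ})`); the implementation solves the
general quadratic so any ratio round-trips to `1e-6` (a property the
test suite checks over random draws).

Two conventions matter for event-wise CN estimation from trial tables:

* **Zero-runoff events are not invertible.** Any sufficiently low CN
  explains `Q = 0`, so such events return `NA` and are excluded from
  averages (with a message, so exclusions are visible).
* **QC-flagged events never enter statistics.** The flag is carried in
  the data (`excluded` column) — e.g. a day on which the runoff
  collection reservoir overflowed — and is never inferred.

Seasonal averages weight each event's CN by its precipitation depth, so
large storms dominate; the weighted mean provably stays inside the
convex hull of the event CNs.

## MUSS erosion and the 2-mm segmentation rule

Event soil loss uses the small-watershed MUSS variant of the Universal
Soil Loss Equation, driven by runoff rather than rainfall erosivity:

$$X_e = 0.79\,(V_r\,q_p)^{0.65}\,A^{0.009}\,K\,LS\,C\,P$$

with `Vr` the event runoff (mm), `qp` the peak runoff rate (mm/h), `A`
the plot area (ha) and the dimensionless erodibility (`K`),
length-slope (`LS`), cover-management (`C`) and support-practice (`P`)
factors. Two points deserve emphasis:

* **`C` is not clamped to 1.** In this framework `C` is the calibrated
  lever that absorbs crop, tillage and residue effects *and* whatever
  the other factors miss; seasonal fits can push it well above one.
  Only its *relative* value between treatments carries meaning.
* **The peak rate is a uniform-rate surrogate.** Daily rainfall is
  segmented into hourly 2-mm steps, `n = min(24, ⌈P/2⌉)`, and the daily
  runoff volume is spread uniformly: `qp = Vr/n`. Field-scale
  simulators use the same segmentation internally but do not document
  their exact `qp`; the uniform rate is the only one consistent with
  the segmentation rule and with the way `n` enters the stream-dilution
  equation below, and it satisfies `qp · n = Vr` exactly. An
  alternative reading of `n` — "hours of the day with simulated
  runoff" — is rejected because the segmentation arithmetic
  (19.9 mm → n = 10) matches `⌈P/2⌉`, not a wetness count.

Units are explicit: `event_soil_loss()` returns tonnes per event for
the whole plot, `soil_loss_per_area()` converts to kg/ha, and the
seasonal summaries expose both kg/ha and t/ha views. No implicit
conversion happens anywhere.

## Season simulation and inverse calibration

`simulate_season()` drives both models through a daily weather series
with **one fixed CN for the whole season**. This is a deliberate
simplification: the regulatory use of the CN concept applies one value
over almost the entire cropping period, and the calibration target is
the seasonal total, not individual events. Antecedent-moisture CN
adjustment, crop-stage CN schedules, evapotranspiration, snow and
irrigation are out of scope (the underlying trials were unirrigated).
Consequences the tests verify: daily runoff never exceeds
precipitation, erosion occurs only on runoff days, seasonal totals are
the sums of the daily series, and the seasonal runoff total is
continuous and nondecreasing in CN.

Calibration follows the two-step order of the season-wise evaluation
strategy:

1. **CN first**: the fitted CN is the *smallest integer* in [30, 100]
   whose simulated seasonal runoff reaches *at least* the measured
   total. Integer reporting mirrors the way such fits are tabulated; a
   continuous root (where the total crosses the target) is returned as
   a diagnostic. Monotonicity makes a grid scan exact; bisection would
   give the identical answer, and the grid over 71 integers is already
   instantaneous at daily-series sizes.
2. **C-factor second, closed-form**: holding the fitted CN, linearity
   of MUSS in `C` gives `C = measured / simulated(C = 1)` exactly; the
   re-simulated seasonal eroded mass reproduces the target to 1e-9
   relative, and recovery of a generating `C` is exact to machine
   precision.

A measured runoff total of zero returns the lower search bound with a
warning (nothing constrains the CN from below); a target beyond the
CN = 100 total raises an "unattainable" error rather than silently
saturating.

## Treatment comparison conventions

Reductions are always `100·(control − treated)/control` for runoff,
erosion and concentrations; CN effects are additionally reported as
point deltas (`control − treated`); C-factor effects as ratios
`treated/control` and relative reductions `1 − ratio`. A ratio above 1
(negative reduction) is legitimate and occurs in the packaged reference
fits: a micro-dam treatment that suppresses runoff strongly can force
the calibrated `C` *up*, because less runoff must still explain the
observed (less-reduced) sediment.

Summary blocks report the arithmetic mean and the **population**
standard deviation (divisor `n`). The choice is empirical:
back-calculating the published "(± sd)" entries from the published
per-season values reproduces them only with the population form (the
test suite checks the n = 6 micro-dam and n = 4 conservation-tillage
blocks; e.g. point deltas 5, 7, 1, 5, 3, 5 give 1.9 with divisor 6 but
2.1 with divisor 5). Report rounding — integers for mm, kg/ha, CN
points and percentages; two decimals for relative C-factors — is
applied only in report views (`report_round()`); all computation is
full-precision.

One published pooled statistic is knowingly not reproduced: the overall
micro-dam runoff/erosion means quoted as 53% (±17) and 68% (±12).
Recomputing every candidate pooling of the printed per-trial reductions
gives 52 (±15) and 65 (±13); the original presumably pooled unrounded
or differently-grouped values. The package emits the computed values
from the printed ones and documents the set used rather than guessing
at hidden inputs; the corresponding conservation-tillage block
(96 ± 3) does reproduce and is part of the acceptance surface.

## The stream mitigation correction

Field-scale mitigation enters a regulatory stream scenario through a
post-processing chain, because the upstream catchment that dilutes the
edge-of-field stream is only partially treated (fraction
`fa = 0.208` in the FOCUS stream). Per runoff day:

1. fractional reductions of pesticide mass flux and runoff volume,
   `fr` and `fv`, from paired unmitigated/mitigated model outputs
   (with `0/0 → 0` by convention, and mitigation assumed never to
   increase a flux);
2. the unmitigated concentration by dilution,
   `PEC = (RFLX/n · fa) / (BASF/24 + raindr·INFLMON/24 + RUNF/n)`,
   with `n` the day's 2-mm segment count, baseflow `BASF = 0.2`
   L/m²/day and leaching-to-baseflow fraction `raindr = 0.1` by
   default;
3. the corrected mitigated concentration
   `PEC_mit = PEC · (1 − fr)/(1 − fa·fv)`.

Units: the mass flux is consumed in mg/m²/day — the unit in which such
worked examples are quoted — while raw field-model output reports
g/cm²/day; `read_exposure(..., rflx_units = "g_cm2_day")` converts
(×1e7) at the boundary instead of guessing inside formulas. The
concentration is returned in µg/L (1000 × the mg/L quotient).

Two structural properties anchor the implementation and are tested:
with `fr = fv` and `fa = 1`, mitigation leaves the concentration
unchanged (equal removal of mass and water from a fully treated
catchment); and `PEC_mit` is decreasing in `fr` and increasing in `fv`.
Days without unmitigated runoff carry zero concentration from this
pathway — baseflow-driven background is not modelled. Applied day-wise,
the correction can move the seasonal maximum to a different date than
the unmitigated maximum, which is why `pec_max()` returns both.

The published worked example is reproduced within the precision of its
printed inputs: with mass fluxes 1.3e-2 vs 4.6e-5 mg/m²/day and volumes
1.6 vs 0.2 L/m²/day, the package computes `fr = 0.9965`, `fv = 0.875`,
an unmitigated 1.556 µg/L on the 19.9-mm day (n = 10) against the
printed 1.61 (the printed inputs are rounded; tolerance 5%), and a
mitigated 6.7e-3 µg/L against the printed 6.82e-3 (checked at 15%,
since it chains every rounding of the inputs).

## The synthetic trial generator

Real per-event trial tables live in supplementary material that is not
machine-readable here, so the package generates its own trials with
known ground truth. The generator emulates the structure of the field
trials: all treatments of a trial share one rainfall season and differ
only in their true `(CN, C)` pair.

* **Rainfall**: wet days are Bernoulli(0.15) over a 180-day season;
  wet-day depths are Gamma(shape 0.8, scale 12) mm. These defaults
  (mean wet-day depth ≈ 9.6 mm, about 27 wet days, regular 20–40 mm
  storms) were chosen once as a realistic episodic regime for a
  temperate maize season of a few hundred mm of rain, matching the kind
  of 5–20+ mm events that dominate trial records; they are parameters
  of `trial_design()`, not constants.
* **Noise**: optional multiplicative lognormal noise (mean 1, relative
  SD `noise_cv`) on measured runoff and eroded mass, reflecting
  volumetric sampling error; off by default so recovery tests are
  exact. Noisy runoff is capped at precipitation to preserve the event
  invariant.
* **Seeding**: every generated object records its integer seed, and
  generation runs in an isolated RNG scope so callers' random streams
  are untouched.

What passing recovery tests show — and what they do not: with zero
noise, `calibrate_season()` recovers the generating CN exactly at
integer granularity and the C-factor to machine precision; under 5%
noise the median fitted CN over 50 seeded replicates stays within one
point of truth. This validates the *inverse machinery*, not the realism
of the generator: real trials add rainfall-intensity variation within
events, redistribution of cumulatively-collected rain, soil-moisture
dynamics and instrument quirks that the generator deliberately omits,
so agreement here does not certify field predictive skill.

## Numerical choices and degenerate inputs

* Problem sizes: tests and the acceptance script run 180-day seasons,
  50-replicate noise studies and 71-point CN grids; everything
  completes in seconds.
* `runoff_depth()` clips to `[0, P]`; the `CN = 100` (S = 0) limit
  yields `Q = P` without special-casing.
* The CN inversion uses the smaller quadratic root (the one keeping
  `P − Ia ≥ 0`) with the discriminant floored at zero against roundoff.
* The continuous CN diagnostic uses `uniroot` at 1e-8 between the
  bracketing integers and degrades to `NA` if no bracket exists.
* Ties in `pec_max()` resolve to the earliest date (`which.max`).
* Readers validate schemas, non-negativity, date ordering and the
  runoff ≤ precipitation invariant, and report the offending row
  numbers; the whitespace-delimited daily-output reader maps columns by
  name and does not promise bit-exact compatibility with any field
  model's file dialect.

## Known limitations

The simulator is not a field-scale fate model: no soil profile, no
evapotranspiration, no antecedent-moisture CN modulation, no pesticide
transport, no sediment routing. Event counts and per-event magnitudes
from a fixed-CN daily loop will not match observed event series — only
seasonal totals are calibration targets, which is precisely the
convention of the season-wise evaluation it mirrors. The stream
correction post-processes daily fluxes; it does not re-run water-body
hydrology, sorption or sediment concentrations, and pond-scenario
concentrations need no correction at all.
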