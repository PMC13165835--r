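---
title: "Models and methods behind the vitidss engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the vitidss engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitidss)
```

vitidss implements the analytical core of a vineyard decision-support
workflow: it turns station observations (or synthetic stand-ins) into
continuous daily weather, derives viticultural indicators from them, and
raises irrigation, disease and phenology alerts. This vignette documents
the models, their assumptions, the defaults, and the choices made where
the underlying methods leave room.

## Weather ingestion and gap-filling

Sub-daily observations arrive at a nominal 30-minute cadence (48 samples
per day). Aggregation to UTC calendar days takes `tmin`/`tmax`/`tmean`
from the temperature samples, sums precipitation, and averages relative
humidity. Timestamps are treated as UTC throughout — the one unambiguous
choice when streams from several providers are merged.

A day qualifies as *complete* when at least 80 % of the expected samples
are present (39 of 48). Below that, the aggregates are still reported but
the day is treated as a gap, because extremes computed from a sparse day
systematically underestimate the true diurnal range. A day with no
temperature samples is never fabricated.

Gap-filling substitutes the *whole* daily record of the nearest national
station that has a complete record for that date. Per-variable blending
was rejected deliberately: a day whose temperature comes from one station
and rain from another has no meaningful provenance, and provenance (donor
id and distance, reported to the user) is the point of the procedure.
Distances are haversine on a sphere of radius 6371.0088 km; equidistant
donors tie-break on lexicographic station id so results are reproducible.
The operation is idempotent — filled days are complete, so a second pass
finds nothing to do.

Malformed rows (unparseable timestamps, humidity outside 0–100 %,
negative rain) are excluded and itemised in a report; ingestion never
aborts on a single bad row. The same plausibility limits are applied to
IoT and national streams alike.

## The synthetic weather generator

Every engine is exercised against generated weather, so the generator is
first-class, tested code. Daily mean temperature is a sinusoid peaking on
day-of-year 205 (late July) plus a stationary AR(1) anomaly whose marginal
standard deviation is `t_noise_sd` (innovations are scaled by
`sqrt(1 - ar1^2)`). Precipitation occurrence follows a two-state Markov
chain started from its stationary probability
`p_wd / (1 - p_ww + p_wd)`; wet-day amounts are Gamma draws. Relative
humidity is a clamped linear response to the temperature anomaly plus a
10-point wet-day bonus.

The defaults describe a Podgorica-like Mediterranean regime — annual mean
15 °C, seasonal amplitude 10 °C, diurnal range 10 °C, roughly 120–130 wet
days a year averaging ~11 mm — chosen once as a realistic fixture, not as
a claim about any site. A single integer seed drives one generator stream
(gap injection uses a fixed offset of that seed), and the caller's RNG
state is left untouched.

Disaggregation back to 30-minute samples uses a continuous diurnal curve
with the minimum at 06:00 and maximum at 15:00; because both extremes fall
exactly on sample times, re-aggregation recovers them exactly.
Per-interval precipitation is the difference of a cumulative ramp, so the
daily total is conserved to the last bit — a property the round-trip tests
assert with `identical()`.

What the generator does *not* emulate: spatial correlation between sites,
weather fronts (anomalies are AR(1), not synoptic), humidity–rain timing
within a day, and wind/pressure. Tests passing on this generator therefore
demonstrate the engines' arithmetic and invariants, not their skill on
real microclimates.

## Thornthwaite evapotranspiration and the Dryness Index

Daily potential evapotranspiration uses the Thornthwaite formulation: the
monthly estimate `16 (10 T / I)^a`, with heat index
`I = Σ (max(0, T_m)/5)^1.514` and the standard cubic exponent `a(I)`,
corrected by photoperiod (`L/12`, from the solar-declination day-length
formula) and divided by the days in the month. Thornthwaite is monthly by
construction; dividing by days-in-month is the documented daily
adaptation here — it preserves monthly totals and needs nothing beyond
temperature, which is exactly what the station suite provides. The heat
index is computed per calendar year from the driving series itself; when a
run covers only part of a year (the April–September seasonal variant, for
instance) missing months fall back to climatological monthly means of the
available data, and a message notes it.

The Dryness Index itself is the recursion `DI_t = min(200, DI_{t-1} + P −
Tv − Es)` with `Tv = k1·ETP` and `Es = (1−k1)·ETP·min(P/5, 1)`. The `min`
factor encodes that bare-soil evaporation requires rain wetting — with no
rain, `Es` is exactly zero. The default `k1` schedule (0.1 off-season,
0.3 in May, 0.5 June–September) follows the Riou/Tonietto dryness-index
convention and is fully configurable. Two windows are exposed: a Jan 1
annual profile for the alert engine, and the April 1–September 30 seasonal
variant whose final value is the bioclimatic dryness index.

Numerical choices: no lower bound is applied to DI (only the upper cap is
part of the recursion), so persistent drought can drive it negative and
the magnitude is informative; the alert comparison is strict (`DI < 50`);
consecutive alert days are grouped into one event carrying the first date
and the run minimum.

## The Goidanich disease engine

Activation and accumulation are deliberately separated. The 3–10 rule is
strict at all three boundaries (rain > 10 mm, temperature > 10 °C, shoots
> 10 cm); once satisfied, activation is latched for the season — resets
zero the index but never de-activate, since the primary inoculum does not
disappear with a spray. Daily increments begin the day after activation
(the activation day registers the infection event itself), and on a reset
day the index *is* zero, with accumulation resuming the next day. These
two timing rules are what make the worked arithmetic come out: with a flat
5 %/day table the index reaches 55 % — its first strict exceedance of
50 % — eleven days after activation, and a spray six days after activation
shifts that crossing by exactly six days.

The shoot-length condition has three configurable sources: a recorded
observation date, an always-true override, and the default GDD proxy
(satisfied once cumulative GDD base 10 from Jan 1 reaches 150 °C·day —
roughly the thermal time to 10 cm shoots on vigorous varieties). The proxy
is the default because shoot observations are sparse in practice.

Automatic mode assumes treatment once risk first strictly exceeds 50 %,
taking effect the next day so the alert remains observable; the test suite
proves this mode equal to manual mode with sprays constructed iteratively
at each first-exceedance-plus-one. Increment-table bins are left-closed,
right-open (topmost bin closed) so a value on an edge belongs to exactly
one cell. The shipped increment table is a simplified one patterned on the
shape of the classic Goidanich tables — fastest development near 20–25 °C
under near-saturated air — and is meant to be replaced by a full
transcription for operational use; all correctness tests run on toy
fixture tables so nothing depends on the shipped values.

## Phenology

Cumulative GDD base 10 °C from Jan 1, with inclusive threshold crossing: a
stage flags on the first day the sum *reaches* its threshold. Inclusive
was chosen because an exactly-met accumulation is the event itself, and it
makes the constant-temperature arithmetic exact (10 °C·day/day crosses a
140 threshold on day 14).

Scenario continuation takes, for every calendar day, the 25th/50th/75th
percentiles of daily mean temperature across the history years (linear
interpolation between order statistics, `quantile` type 7); Feb 29
observations are pooled into Feb 28. Stages crossed inside the observed
window are reported once, scenario `observed`, because every continuation
shares that prefix. Two properties pin the semantics down: pointwise
warmer continuations never delay any stage, and extending the observed
window with the median scenario's own values never changes the
median-scenario forecast.

Field BBCH records are validated against the standard observation ranges
(11–29, 53–57, 60–69, 71–79, 81–89, 91–99) plus the calibrated stage code
07, future dates are rejected, and duplicates of (parcel, variety, stage,
date) are flagged — as a report, never an exception, since a rejected
record is information the grower should see.

## Bioclimatic indices and ensemble normals

The growing season is fixed to April 1–October 31 (Huglin window April
1–September 30) per the index literature. Note the Apr–Oct window always
contains 214 days — leap days fall outside it — while annual totals see
366. BEDD is implemented in its simple capped form (daily contribution
limited to 9 °C·day) without the diurnal-range adjustment. The Huglin
coefficient uses the standard stepwise latitude table (1.00 below 40°
through 1.06 at 48–50°). The Branas hydrothermal index — for which no
single canonical formulation exists — is defined here as the April–August
sum of monthly mean temperature times monthly precipitation; the extremes
set is a minimal ETCCDI-style six (frost days, summer days, tropical
nights, hot days, rx1day, cdd with a 1 mm wet-day threshold). Ensemble
normals are the mean over models of per-model period means, which for
equal coverage equals the grand mean — asserted against brute force in the
tests. Inputs are assumed Gregorian daily tables; 360/365-day model
calendars are out of scope.

## The yield simulator

The growth engine is intentionally minimal: daily biomass gain
`RUE · PAR · (1 − exp(−k·LAI)) · f(FTSW)`, a linear FTSW stress ramp below
`ftsw_crit`, LAI ramping linearly with thermal time toward its ceiling, a
constant post-anthesis partition fraction to fruit, and a one-bucket soil
store whose losses are canopy-scaled Thornthwaite ETP. Incident PAR is
estimated from the diurnal temperature range via Hargreaves–Samani
(`Rs = 0.16 √(tmax − tmin) · Ra`, PAR = 0.5 Rs), because the station suite
measures no radiation. Anthesis (492 °C·day) and maturity (2188 °C·day)
reuse the Vranac calibration so the phenology and yield engines agree on
timing.

Every functional form is a documented default with its constant exposed in
`vine_sim_config()`; none is calibrated against observed yields, and
simulated absolute yields should be read as relative responses (to water,
canopy management, and climate scenarios), not predictions. The properties
the engine does guarantee — and the tests enforce — are bookkeeping ones:
fruit never exceeds total biomass, both are non-decreasing, soil water
stays in `[0, TTSW]` with `FTSW = ATSW/TTSW` exactly, fruit stays zero
until anthesis, yield is exactly linear in RUE, and extra water (rain or
irrigation) never reduces yield.

## Problem sizes and determinism

The test suite builds everything it needs in code: single constant years
for closed-form checks, 30 years of synthetic weather for the generator's
long-run statistics, 100-seed batches for the mode-equivalence and
forecast-dominance properties, and 1000 fuzzed sub-daily streams for the
aggregation invariants. These sizes were chosen so each property is
exercised across the regime of interest while the whole suite stays quick
to iterate on. All stochastic tests fix their seeds; the command-line
interface is deterministic given identical inputs and seed, which the CLI
test asserts byte-for-byte.

## Known limitations

* The Goidanich increment table shipped is illustrative, not a
  transcription; operational deployments must supply their own.
* Thornthwaite ETP underestimates in windy/advective conditions; no
  Penman-type alternative is wired in because the sensor suite lacks the
  inputs.
* Gap-filling substitutes station records without elevation or distance
  weighting — the donor's weather stands in unmodified, which is honest
  but crude in mountainous terrain.
* The phenology scenarios are percentiles of history; they carry no
  warming trend unless the history does.
* The yield simulator has no berry-number component, carbon reserves, or
  quality variables, and its absolute level is uncalibrated.
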