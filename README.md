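# vitidss

Agro-climatic decision-support engines for viticulture, packaged as a
tested R library with a command-line interface. The package targets the
analytical layer a vineyard platform needs between raw weather-station
streams and grower-facing alerts: quality control and daily aggregation of
30-minute sensor data, nearest-station gap-filling, viticultural
bioclimatic indices and multi-model climate normals, an irrigation alert
based on a recursive soil-water-balance Dryness Index, a Goidanich
downy-mildew risk index with the 3–10 activation rule, growing-degree-day
phenology forecasting for calibrated grape varieties (Vranac ships as the
default), and a minimal radiation-use-efficiency yield simulator. A seeded
stochastic weather generator makes every engine testable without any
external data.

## The models

**Dryness Index (irrigation).** A daily soil water balance initialised at a
200 mm reserve:

    DI_t = min(200, DI_{t-1} + P_t − Tv_t − Es_t),
    Tv_t = k1 · ETP_t,     Es_t = (1 − k1) · ETP_t · min(P_t / 5, 1)

where `P_t` is daily precipitation (mm), `ETP_t` the daily Thornthwaite
potential evapotranspiration (computed from mean temperature, photoperiod
and the annual heat index `I = Σ (T_m/5)^1.514`), and `k1` a seasonal crop
coefficient. Days with `DI < 50` mm raise an irrigation alert. Without
rain, `Es = 0`: bare-soil evaporation only acts when rain wets the surface.

**Goidanich index (downy mildew).** Primary infection triggers when the
3–10 rule holds (rain > 10 mm/24 h, mean temperature > 10 °C, shoot length
> 10 cm, all strict). From activation the cumulative risk accumulates
daily,

    GI_t = min(100, GI_{t-1} + f(T_t, RH_t)),

with `f` looked up in a temperature × relative-humidity increment table.
Alerts fire strictly above 50 %; recorded sprays reset `GI` to zero
(manual mode), or a treatment is assumed the day after first exceedance
(automatic mode), or both (hybrid).

**Phenology (GDD).** Cumulative growing degree days base 10 °C from Jan 1.
Vranac stage thresholds: BBCH 07 (bud burst) at 139, BBCH 65 (full
flowering) at 492, BBCH 81 (veraison) at 1203, BBCH 89 (harvest ripeness)
at 2188 °C·day. Observed temperatures are continued to year end with the
25th/50th/75th daily percentiles of a multi-year history (cold / median /
hot scenarios); each new day of sensor data shrinks the forecast spread.

**Bioclimatic indices.** Winkler (= GDD₁₀ over Apr 1–Oct 31), biologically
effective degree days (daily contribution capped at 9), Huglin (Apr 1–Sep
30 with the latitude day-length coefficient K), cool-night index, seasonal
dryness index, Branas hydrothermal index, De Martonne aridity index, and an
ETCCDI-style extremes set — plus ensemble climate normals (mean over GCMs
of per-model period means).

**Yield.** Daily biomass gain `ΔB = RUE · PAR · (1 − e^(−k·LAI)) · f(FTSW)`
with a linear FTSW stress ramp, GDD-driven LAI, post-anthesis partitioning
to fruit, and management coupling (trimming caps LAI, irrigation refills
the soil store). Yield is fruit dry biomass at the maturity GDD threshold.

## Worked example

```r
library(vitidss)

params <- weather_gen_params(seed = 42)            # Podgorica-like regime
daily  <- generate_daily_weather(params, 2025, 1, site_id = "vineyard-1")

di <- run_dryness_index(daily, lat = 42.44)
print(di)
#> Dryness Index series: 365 days (2025-01-01 to 2025-12-31)
#>   final DI 200.0 mm; minimum 170.3 mm; 0 alert day(s)

gi <- run_goidanich(daily, params = goidanich_params(mode = "manual"))
print(gi)
#> Goidanich risk series: 365 days (2025-01-01 to 2025-12-31)
#>   activated 2025-05-17; max GI 100.0%; 207 alert day(s); 0 reset(s)

hist <- generate_daily_weather(weather_gen_params(seed = 7), 2015, 10)
scen <- build_climatology_scenarios(hist)
print(forecast_stage_dates(daily[1:135, ], scen, vranac_calibration()))
#> Stage forecasts for Vranac:
#>   BBCH 07 [observed]: 2025-05-04 (GDD 140)
#>   BBCH 65 [cold]: 2025-06-15 (GDD 502)
#>   ...
#>   BBCH 89 [median]: 2025-11-07 (GDD 2188)
#>   BBCH 89 [hot]: 2025-10-05 (GDD 2190)
```

The wet synthetic year keeps the soil reserve pinned near its 200 mm cap
(no irrigation alerts — the expected winter-season behaviour), while the
frequent warm rain drives the mildew index to saturation. Bud burst was
crossed inside the observed window (reported once, scenario `observed`);
later stages spread out across the cold/median/hot continuations —
harvest ripeness is not reached at all under the cold scenario.

The same engines are scriptable from a shell:

```sh
inst/cli/vitidss simulate-weather --seed 5 --start-year 2025 --years 1 --out daily.csv
inst/cli/vitidss irrigation --daily daily.csv --lat 42.44 --out di.csv
inst/cli/vitidss disease    --daily daily.csv --mode hybrid --out gi.csv
```

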