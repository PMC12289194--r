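# boarheat

Analysis pipeline for wild boar (*Sus scrofa*) activity under summer weather,
built on multisensor biologging collars: triaxial accelerometry, hourly
weather, and GPS telemetry. The package asks how heat and rain reshape a
nocturnal ungulate's activity budget — hour by hour, across the summer
season, and within heatwaves — and ships a synthetic-data generator with the
statistical structure the analysis assumes, so the whole pipeline runs and is
tested without any field data.

## What it computes

**VeDBA.** Movement-based energy expenditure is proxied by the vectorial sum
of dynamic body acceleration. Per axis, the static (gravitational) component
is a 2 s centred rolling mean; the dynamic component is the raw signal minus
the static estimate, and

```
VeDBA_t = sqrt(dx_t^2 + dy_t^2 + dz_t^2)
```

smoothed again over 2 s ("smoothed VeDBA"), summed per hour, and averaged
over sunrise-anchored *biological days* (sunrise on day *d* to sunrise on
day *d*+1, keeping one nocturnal active phase intact). Sunrise and sunset
come from the NOAA solar-position equations at solar elevation −0.833°.

**Heatwaves.** A biological day qualifies when its mean temperature strictly
exceeds 24 °C — the upper bound of the species' summer thermoneutral zone —
with at least 23 h of data coverage; a heatwave is a maximal run of
consecutive qualifying days.

**Movement.** GPS fixes pass a dilution-of-precision filter (1 ≤ DOP ≤ 7);
per biological day the pipeline reports distance travelled (summed haversine
step lengths), maximum net squared displacement from the day's first fix,
and mean step speed.

**Models.** Three structures, all Gaussian (identity link) with a random
animal intercept:

| model | response | fixed effects |
|---|---|---|
| diel GAMM | hourly VeDBA sum | `s(temp) + s(hour, cyclic) + ti(temp, hour)`, each split by hourly precipitation presence, plus its main effect (REML) |
| seasonal GAMM | daily mean VeDBA, or a movement metric | `s(tmax) + s(DOY) + ti(tmax, DOY)`, split by daily precipitation presence (REML) |
| heatwave LMM | per-animal mean daily VeDBA within a heatwave | z-scored mean daily maximum temperature and heatwave length, precipitation presence, both interactions (ML; Nakagawa marginal/conditional R²) |

Effect summaries include `percent_change()` between clock windows (e.g.
late afternoon to around sunset) and `night_day_elevation()`, the predicted
activity elevation of the 22:00–04:00 window over 05:00–21:00.

## Worked example

```r
library(boarheat)
library(dplyr)

cfg    <- sim_config(seed = 1)                  # 3 boars, June-August, 50 N
weather <- sim_weather(cfg)
solar   <- solar_table(49.96, 14.78, cfg$start, cfg$end, tz_offset = 2)
hourly  <- sim_activity_hourly(cfg, weather, solar)

fit <- hourly |>
  mutate(precip = precip_binary(precip_mm)) |>
  fit_gam_hourly()
fit
#> Activity GAMM (hourly scale), response: vedba_sum
#>   Gaussian (identity), REML; random animal intercept; smooths split by precipitation
#>   n = 6624, adj. R2 = 0.728, deviance explained = 0.729

percent_change(fit, 16:17, 20:21, temp = 30, precip = "absence")
#> [1] 124.0635
night_day_elevation(fit)
#> [1] 56.9943
```

The boars in this simulated world are strongly nocturnal (activity ~57%
higher in the 22:00–04:00 window than in 05:00–21:00) and ramp up steeply
from late afternoon to dusk; the rise is larger on hot dry days (+124.1% at
30 °C vs +100.2% at 15 °C) because heat suppresses the afternoon baseline the
rise is measured against. `autoplot(fit)` and `plot_diel(fit)` draw the
partial effects and the predicted diel curve; `tidy()`/`glance()` return the
term table and fit statistics.

`run_pipeline(demo_run_config("run"))` executes the whole chain — simulate,
VeDBA from a 10 Hz stream, biological-day aggregation, weather join,
heatwave detection, movement metrics, the three models, contrasts — writing
stage-numbered CSVs, a fit report and a JSON manifest of per-stage row
counts under `run/`. Reruns with the same seed are byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full demonstration pipeline from scratch at the given seed
(every stage above, ending in the fitted models and contrast table printed
to the console) and writes the JSON report to `--out`.

## Package layout

- `R/simulate.R` — synthetic weather, hourly activity with ground truth,
  10 Hz accelerometer synthesis, GPS random walks, heatwave-level tables
- `R/accel.R`, `R/solartime.R` — VeDBA stack and sunrise-anchored days
- `R/weather.R`, `R/heatwave.R`, `R/movement.R` — covariate assembly,
  heatwave detection, movement metrics
- `R/models.R`, `R/tidiers.R` — the three models, contrasts, broom-style
  methods and plots
- `R/pipeline.R` — orchestration, manifest, logging
- `vignettes/boarheat-methods.Rmd` — model assumptions, generator design,
  numerical choices and limitations
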