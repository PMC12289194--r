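---
title: "Methods: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic worlds and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
assumes, why the tunable parameters have the defaults they have, what the
synthetic-data generator does and does not emulate, and where the design was
genuinely open and a choice had to be made. It states no empirical result
that the test suite does not itself compute.

## 1. From raw acceleration to activity

A collar-mounted triaxial accelerometer at 10 Hz measures gravity plus body
motion. The gravitational (static) component is estimated per axis by a
centred rolling mean over 2 s — 21 samples at 10 Hz (nearest odd count) —
and subtracted; the Euclidean norm of the three dynamic components is the
per-sample VeDBA, which is smoothed again with the same 2 s centred window
("smoothed VeDBA"). Two numerical policies matter at the edges:

* **Shrinking windows.** Edge samples average over whatever part of the
  window exists, so no data are lost at stream or hour boundaries. The
  alternative (dropping half-windows) would bite 2 s out of every recording
  gap and complicate the hourly conservation property (the sum of hourly
  sums equals the sum of all smoothed samples).
* **Gap breaking.** Gaps longer than 1 s split the stream; a rolling window
  never spans a recording gap, since a mean across a gap would blend
  unrelated postures.

The order of operations — static per axis, then the norm, then smoothing of
the norm — is the conventional reading of a "smoothed VeDBA" export from
tag-vendor software; the alternative order (smoothing the absolute per-axis
dynamics before the norm) is available via the `order` argument of
`vedba()`, since vendor documentation does not pin this down.

Hourly sums are indexed by local clock hour and by *biological day*: sunrise
on day *d* to sunrise on day *d*+1, so the nocturnal active phase of a
nocturnal species is never split across day labels. An hourly bin that
straddles sunrise is assigned to the biological day containing the bin's
start, keeping bins atomic. Hours with less than 80% of expected samples
are flagged and excluded from daily means; biological days with fewer than
20 qualifying hours are dropped. Both thresholds are package inventions
(the analysis tradition is silent on missingness) and are exposed as
arguments.

## 2. Solar geometry

Sunrise and sunset use the NOAA low-accuracy solar-position series
(fractional-year expansion of declination and the equation of time) at
solar elevation −0.833°, i.e. standard refraction plus the solar disc. The
closed-form hour-angle inversion is iterated three times so the declination
is evaluated at the event rather than at noon; the remaining error against
a minute-grid elevation scan is well under the ±2 min tolerance the tests
enforce. Polar day/night return an explicit no-event flag — never a default
time — and downstream biological-day assignment refuses polar tables. A
single site coordinate serves all animals: across a study area of a few
kilometres sunrise varies by seconds. The local clock is a fixed UTC offset
(UTC+2); June–August avoids DST transitions, so no timezone database is
needed and determinism is trivial.

## 3. Weather, heatwaves, movement

Precipitation is a strict binary: presence iff the total exceeds 0 mm, no
trace threshold. Weather hours aggregate to the same sunrise-anchored days
as activity so response and covariates share one clock (a calendar-day mode
exists for providers that report calendar days; the two differ only in
which pre-dawn hours a day owns).

A heatwave day must exceed 24 °C in daily *mean* temperature — the upper
bound of the wild boar's summer thermoneutral zone — strictly, with at
least 23 hourly records covering the day. The "23+ h" clause is read as a
data-coverage requirement, not a rolling 23 h window, because heatwave
lengths are reported in whole days; single-day heatwaves count. Heatwaves
are maximal runs of consecutive qualifying days; gaps in the daily series
split runs and are logged.

Movement metrics are computed on a 6371 km sphere (haversine); at the
spatial scale of a forest home range the spherical-versus-projected
difference is far below GPS error. Net squared displacement is anchored at
the day's first fix — the natural "how far did it range today" reading when
no burrow-like central place is known. Steps whose duration exceeds four
nominal fix intervals are excluded from distance and speed (a step across a
fix outage is not a travelled path) but kept for NSD, which needs no path.

## 4. The three models

All models are Gaussian with identity link and a random animal intercept,
matching the tradition of modelling a strictly positive but roughly
symmetric activity index on its natural scale.

* **Diel model** (`fit_gam_hourly`): hourly VeDBA sum on a thin-plate
  temperature smooth, a *cyclic cubic* hour smooth (knots tied at 0 = 24 so
  predictions at midnight match from both sides), and a tensor-product
  interaction `ti(temp, hour)`, each split by the hour's precipitation
  presence, plus the presence main effect. REML throughout.
* **Seasonal model** (`fit_gam_seasonal`): daily mean VeDBA (or a movement
  metric) on daily maximum temperature and day-of-year smooths with their
  `ti` interaction, split by the day's precipitation presence. DOY is not
  cyclic: a three-month window has no periodicity to close.
* **Heatwave model** (`fit_lmm_heatwave`): per-animal mean daily VeDBA per
  heatwave on z-scored mean daily maximum temperature and length, presence,
  and the two interactions; fitted by ML. Marginal and conditional R²
  follow the Nakagawa variance-partition formulae, computed directly from
  the variance components.

Basis dimensions default to k = 10 for univariate smooths and 5×5 for
tensor interactions — the customary mgcv-scale defaults — and are exposed
(`k`, `k_hour`, `k_ti`) because basis adequacy is an empirical question:
when an estimated degrees-of-freedom saturates its ceiling (the
`gam.check` criterion) the basis must grow. A degenerate constant response
cannot drive REML smoothness estimation; the fit then pins all smoothing
parameters high and collapses cleanly to the constant, with a warning.

### Contrasts

`percent_change()` compares population-level predictions (random intercept
at zero) averaged over two clock-hour windows at a fixed temperature and
precipitation level. `night_day_elevation()` is the headline diel contrast:
the 22:00–04:00 window (hour bins 22, 23, 0–3, wrapping midnight) over
05:00–21:00 (bins 5–20), averaged over the observed temperature
distribution (decile grid) and both precipitation levels weighted by their
observed frequency. Prediction grids use the integer hour-bin labels the
model was fitted on — evaluating between design points would not reflect
any observed covariate value. Windows are half-open hour intervals, so
"16:00 to 18:00" means bins {16, 17}.

## 5. The synthetic world

The generator exists so that every downstream stage has a testable input
with known truth. Its defaults describe one fixed world — a central
European lowland forest summer — and are not tuned per test:

* **Temperature**: seasonal level 17.8 °C + 2.5 °C cosine peaking at DOY
  200, a 5.5 °C diel cosine peaking at 15:00, hourly AR(1) noise (sd
  1.3 °C, φ 0.85), and five injected warm spells (1–3 days, +4.5–5 °C on
  the daily mean) that push daily means above the 24 °C threshold — giving
  heatwave counts and lengths of the magnitude a three-summer central
  European record shows, since natural exceedance of the threshold is rare
  in this climate.
* **Precipitation**: 42% of days dry; wet days draw per-hour wet indicators
  (rate 0.15) with exponential amounts (mean 0.8 mm) and at least one wet
  hour (a "wet day" with zero total would contradict its own label).
* **Activity** is *semi-additive*: a diel baseline — 3600 VeDBA units
  scaled by a nocturnal multiplier of 1.6 and by dusk/dawn acrophase bumps
  (amplitudes 0.7/0.5, width 1.5 h, centred on the day's actual sunset and
  sunrise) — plus an additive temperature slope (−80 units/°C on dry days,
  0 on wet days), a seasonal trend of −6 units/day, a Gaussian individual
  intercept (sd 500) and Gaussian residual noise (sd 1000), truncated at
  zero. Two design points deserve emphasis:
  * The nocturnal multiplier ramps smoothly (cosine, ±1 h) around sunrise
    and sunset rather than switching instantaneously. Animals do not
    teleport between activity states, and a square-wave diel truth is
    unrecoverable by *any* smooth diel model — the cyclic spline saturates
    its basis at every dimension tried and systematically attenuates the
    night/day contrast. A smooth crepuscular transition is both the more
    realistic world and the one in which the model family's estimand is
    well defined.
  * The additive structure (slopes in VeDBA units per °C, a random
    *intercept*, additive residual) is deliberately the world a
    Gaussian-identity additive GAMM is built for. An earlier fully
    log-linear variant (multiplicative temperature effect, lognormal
    noise) was abandoned: it places a strong hour×temperature product
    interaction in data regions the design never observes, so the fitted
    contrast drifted with the evaluation temperature and recovery of the
    injected nocturnal elevation was structurally biased low.
* **10 Hz streams** (`sim_accel`): a slowly rotating gravity unit vector
  plus band-limited (1–3 Hz) sinusoid carriers under Hann-windowed burst
  envelopes, with per-hour amplitude normalised by the envelope mass so the
  hourly VeDBA sum tracks the intended intensity. Burst timing is shared
  across animals, so individual effects are a pure amplitude scaling — a
  construction property the tests exploit. A full season at 10 Hz is ~80 M
  samples per animal; streams are therefore synthesized for short spans
  (the accelerometer stack's tests) while season-scale model tests use the
  hourly-fidelity stream directly, with the intended intensity emitted as a
  sidecar truth column.
* **GPS**: an AR(1) pull toward a home-range centre (step sd 100 m,
  attraction 0.95, 30 min fixes) and a DOP distribution in which a
  configured fraction (default 10%) falls outside the [1, 7] quality
  window.

What the generator does **not** emulate: behaviour-level structure
(foraging vs travelling bouts), terrain or habitat heterogeneity,
magnetometer channels, tag drift or clock skew, and weather-station
interpolation error. A green recovery test therefore establishes that the
pipeline recovers the effects *it injects* under realistic noise — not that
the field system is free of the confounds the generator omits.

## 6. Known limitations and open edges

* Smooth-term p-values are approximate; under a true null the wet-branch
  temperature smooth (which sees only ~9% of hourly rows) shows a type-I
  rate nearer 0.10 than the nominal 0.05. The calibration test budgets for
  this; substantive conclusions should rest on effect shapes and
  magnitudes, not marginal p-values.
* The night/day elevation of a single 5-animal season carries ±3–4
  percentage points of sampling noise from the individual-intercept draw
  alone; recovery is assessed on the mean across replicate simulations.
* The heatwave model is estimable only with several heatwaves and animals;
  the pipeline skips it (with a log entry) below 2 heatwaves, 2 animals or
  8 observations rather than fitting a rank-deficient design.
* Truncation of simulated activity at zero slightly sweetens the extreme
  hot-dry tail; at the default parameters the affected probability mass is
  a few percent of the worst-case cells.
* The generator's dry/wet temperature slopes act at day level while the
  diel model codes precipitation per hour; dry hours of wet days therefore
  dilute the dry-branch slope estimate. This mirrors the real ambiguity of
  hourly precipitation coding and is left in place deliberately.
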