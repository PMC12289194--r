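# Synthetic biologging inputs with the statistical structure the analysis
# assumes: a summer temperature cycle with injected heatwaves, ~42% dry days,
# nocturnal-dominant activity with dusk/dawn acrophases and a negative
# temperature effect confined to dry days, plus GPS fixes from a biased
# correlated random walk. Two fidelity levels: full 10 Hz streams for short
# spans (to exercise the accelerometer stack) and direct hourly VeDBA sums
# for season-long model tests.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a central-European suburban forest summer (June-August
#' 2019 at 50 N): daily mean temperature near 19-20 C peaking mid-July, a
#' diel swing peaking mid-afternoon, 42% of days without precipitation, and
#' five injected multi-day warm spells that push the daily mean above the
#' 24 C wild-boar thermoneutral ceiling. Activity is log-linear: a baseline
#' hourly VeDBA sum, a 1.6x nocturnal multiplier, dusk/dawn acrophase bumps,
#' a negative temperature slope on dry days only, a declining seasonal trend,
#' lognormal individual intercepts and residual noise.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param n_animals number of simulated individuals.
#' @param start,end study window (Dates); default June 1 - Aug 31 2019.
#' @param site list: `lat`, `lon` (decimal degrees), `tz_offset` (hours).
#' @param temp list: `base_mean_c` seasonal level, `seasonal_amp_c` and
#'   `seasonal_peak_doy` of the annual cosine, `diel_amp_c` and
#'   `diel_peak_hour` of the within-day cosine, AR(1) hourly noise
#'   (`ar_sd_c`, `ar_phi`), and `heatwaves`: list of
#'   `list(start_day, length_days, boost_c)` additive daily-mean boosts
#'   (1-based day index from `start`).
#' @param precip list: `p_dry` dry-day probability (default 0.42),
#'   `wet_hour_rate` per-hour wet probability within wet days,
#'   `wet_hour_mean_mm` mean rainfall of a wet hour.
#' @param activity list: `baseline` hourly VeDBA sum at the reference
#'   temperature/DOY for a daytime hour, `nocturnal_mult` with its
#'   crepuscular transition half-width `twilight_h` (hours; 0 gives a hard
#'   day/night step), acrophase
#'   amplitudes/width (`dawn_amp`, `dusk_amp`, `acro_width_h`; amplitudes
#'   are fractions of the diel baseline),
#'   `temp_slope_dry`/`temp_slope_wet` (VeDBA units per C), `temp_ref_c`,
#'   `doy_trend` (VeDBA units per day), `indiv_sd` and `resid_sd`
#'   (VeDBA units).
#' @param gps list: `step_sd_m` per-fix displacement scale, `attract`
#'   pull toward the home-range centre (AR coefficient), `fix_interval_min`,
#'   `dop_bad_frac` fraction of fixes whose DOP falls outside `[1, 7]`.
#' @param accel list for the 10 Hz synthesis: `rate_hz`,
#'   `burst_rate_per_min`, `burst_dur_s` (range), `carrier_band_hz` (range).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_animals = 3L,
                       start = as.Date("2019-06-01"),
                       end = as.Date("2019-08-31"),
                       site = list(lat = 49.96, lon = 14.78, tz_offset = 2),
                       temp = list(),
                       precip = list(),
                       activity = list(),
                       gps = list(),
                       accel = list()) {
  temp_def <- list(
    base_mean_c = 17.8, seasonal_amp_c = 2.5, seasonal_peak_doy = 200,
    diel_amp_c = 5.5, diel_peak_hour = 15, ar_sd_c = 1.3, ar_phi = 0.85,
    heatwaves = list(
      list(start_day = 25, length_days = 3, boost_c = 5.0),
      list(start_day = 40, length_days = 1, boost_c = 4.5),
      list(start_day = 55, length_days = 2, boost_c = 5.0),
      list(start_day = 70, length_days = 1, boost_c = 4.5),
      list(start_day = 82, length_days = 2, boost_c = 5.0)
    )
  )
  precip_def <- list(p_dry = 0.42, wet_hour_rate = 0.15, wet_hour_mean_mm = 0.8)
  activity_def <- list(
    baseline = 3600, nocturnal_mult = 1.6, twilight_h = 1,
    dawn_amp = 0.5, dusk_amp = 0.7, acro_width_h = 1.5,
    temp_slope_dry = -80, temp_slope_wet = 0, temp_ref_c = 20,
    doy_trend = -6, indiv_sd = 500, resid_sd = 1000
  )
  gps_def <- list(step_sd_m = 100, attract = 0.95, fix_interval_min = 30,
                  dop_bad_frac = 0.1)
  accel_def <- list(rate_hz = 10, burst_rate_per_min = 3,
                    burst_dur_s = c(2, 10), carrier_band_hz = c(1, 3))

  cfg <- list(
    seed = as.integer(seed),
    n_animals = as.integer(n_animals),
    start = as.Date(start), end = as.Date(end),
    site = site,
    # modifyList would merge the unnamed heatwave list element-wise; the
    # injection list must be replaced wholesale
    temp = {
      t_merged <- utils::modifyList(temp_def, temp)
      if ("heatwaves" %in% names(temp)) t_merged$heatwaves <- temp$heatwaves
      t_merged
    },
    precip = utils::modifyList(precip_def, precip),
    activity = utils::modifyList(activity_def, activity),
    gps = utils::modifyList(gps_def, gps),
    accel = utils::modifyList(accel_def, accel)
  )
  if (cfg$end < cfg$start) {
    stop("empty date range: `end` precedes `start`", call. = FALSE)
  }
  with(cfg$precip, stopifnot(p_dry >= 0, p_dry <= 1))
  stopifnot(cfg$temp$ar_sd_c >= 0, cfg$activity$indiv_sd >= 0,
            cfg$activity$resid_sd >= 0, cfg$n_animals >= 1)
  structure(cfg, class = "sim_config")
}

.animal_ids <- function(cfg) sprintf("A%02d", seq_len(cfg$n_animals))

.seasonal_temp <- function(cfg, doy) {
  cfg$temp$base_mean_c +
    cfg$temp$seasonal_amp_c * cos(2 * pi * (doy - cfg$temp$seasonal_peak_doy) / 365)
}

.heatwave_boost <- function(cfg, day_index) {
  boost <- numeric(length(day_index))
  for (hw in cfg$temp$heatwaves) {
    hit <- day_index >= hw$start_day & day_index < hw$start_day + hw$length_days
    boost[hit] <- boost[hit] + hw$boost_c
  }
  boost
}

#' Simulate an hourly weather table
#'
#' One record per hour of the study window, aligned to local calendar days.
#' Temperature is seasonal level + diel cosine (peak mid-afternoon) + AR(1)
#' noise + injected heatwave boosts. Precipitation is zero on dry days
#' (probability `p_dry`); wet days draw per-hour wet indicators and
#' exponential amounts, with at least one wet hour guaranteed.
#'
#' @param config a [sim_config()].
#' @return tibble with `t` (POSIXct UTC, start of hour), `temp` (C),
#'   `precip` (mm).
#' @export
sim_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  days <- seq(cfg$start, cfg$end, by = "day")
  n_days <- length(days)
  off <- cfg$site$tz_offset * 3600
  t0 <- utc_posix(as.POSIXct(cfg$start, tz = "UTC")) - off
  t <- t0 + (seq_len(n_days * 24) - 1) * 3600
  day_idx <- rep(seq_len(n_days), each = 24)
  h_local <- rep(0:23, times = n_days)
  doy <- doy_of(days)[day_idx]

  base <- .seasonal_temp(cfg, doy) +
    cfg$temp$diel_amp_c * cos(2 * pi * (h_local - cfg$temp$diel_peak_hour) / 24) +
    .heatwave_boost(cfg, day_idx)

  n <- length(t)
  ar <- numeric(n)
  if (cfg$temp$ar_sd_c > 0) {
    innov_sd <- cfg$temp$ar_sd_c * sqrt(1 - cfg$temp$ar_phi^2)
    e <- rnorm(n, 0, innov_sd)
    ar[1] <- rnorm(1, 0, cfg$temp$ar_sd_c)
    for (i in 2:n) ar[i] <- cfg$temp$ar_phi * ar[i - 1] + e[i]
  } else {
    # consume the same number of draws so downstream streams stay aligned
    rnorm(n + 1)
    ar[] <- 0
  }

  dry <- runif(n_days) < cfg$precip$p_dry
  precip <- numeric(n)
  for (d in seq_len(n_days)) {
    u <- runif(24)
    amt <- rexp(24, rate = 1 / cfg$precip$wet_hour_mean_mm)
    if (!dry[d]) {
      wet_h <- u < cfg$precip$wet_hour_rate
      if (!any(wet_h)) wet_h[which.min(u)] <- TRUE
      precip[(d - 1) * 24 + which(wet_h)] <- amt[wet_h]
    }
  }

  tibble::tibble(t = t, temp = base + ar, precip = precip)
}

.acro_bump <- function(h, centre, amp, width) {
  amp * exp(-0.5 * (hour_dist(h, centre) / width)^2)
}

# Smooth nocturnal weight: 1 deep in the night, 0 deep in the day, cosine
# ramps of half-width `tw` hours around sunrise and sunset. Animals do not
# switch activity discontinuously at the horizon crossing; an instantaneous
# step would also be unrecoverable by any smooth diel model.
.night_weight <- function(h, sunrise_h, sunset_h, tw) {
  if (tw <= 0) {
    return(as.numeric(h < sunrise_h | h >= sunset_h))
  }
  ramp <- function(p) 0.5 * (1 - cos(pi * pmin(1, pmax(0, p))))
  rise <- ramp((h - (sunrise_h - tw)) / (2 * tw)) # 0 -> 1 across dawn
  fall <- ramp((h - (sunset_h - tw)) / (2 * tw))  # 0 -> 1 across dusk
  1 - rise * (1 - fall)
}

#' Simulate hourly activity (VeDBA sums) with known ground truth
#'
#' Season-scale fidelity level: emits the intended (noise-free) hourly VeDBA
#' sum `mu_truth` alongside the observed lognormal draw `vedba_sum`, so
#' recovery tests never re-derive truth from the generator's internals.
#' The intensity model is semi-additive: a diel baseline — the base level
#' scaled by the nocturnal multiplier (weighted by a smooth night weight:
#' cosine ramps of half-width `twilight_h` around sunrise and sunset) and by
#' dusk/dawn acrophase bumps centred on the day's actual sunrise/sunset —
#' plus an additive temperature slope (negative on dry local calendar days,
#' null on wet ones by default), a linear DOY trend, a Gaussian individual
#' intercept and Gaussian residual noise, truncated at zero.
#'
#' @param config a [sim_config()].
#' @param weather hourly weather table from [sim_weather()] covering the window.
#' @param solar optional solar table; computed from `config$site` if missing.
#' @return tibble with one row per animal x hour: `animal_id`, `t_hour`,
#'   `bio_day`, `clock_hour`, `doy`, `night`, `temp`, `precip_mm`, `day_dry`,
#'   `mu_truth`, `vedba_sum`.
#' @export
sim_activity_hourly <- function(config, weather, solar = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  act <- cfg$activity
  if (is.null(solar)) {
    solar <- solar_table(cfg$site$lat, cfg$site$lon, cfg$start, cfg$end,
                         cfg$site$tz_offset)
  }
  set.seed(cfg$seed + 1L)
  b <- rnorm(cfg$n_animals, 0, act$indiv_sd)

  off <- cfg$site$tz_offset
  w <- weather
  ld <- local_date(w$t, off)
  day_tot <- tapply(w$precip, ld, sum)
  day_dry <- as.vector(day_tot[as.character(ld)]) == 0
  h_mid <- local_hour(w$t, off) + 0.5
  night <- day_night(w$t + 1800, solar) == "night"
  bio_day <- assign_bio_day(w$t, solar)

  i <- match(ld, solar$date)
  dawn_h <- (as.numeric(solar$sunrise[i]) %% 86400) / 3600 + off
  dusk_h <- (as.numeric(solar$sunset[i]) %% 86400) / 3600 + off

  night_w <- .night_weight(h_mid, dawn_h, dusk_h, act$twilight_h)

  # semi-additive intensity: a diel baseline (nocturnal multiplier and
  # acrophase bumps scale the baseline) plus additive temperature, seasonal
  # and individual terms — the structure a Gaussian identity GAMM assumes
  slope <- ifelse(day_dry, act$temp_slope_dry, act$temp_slope_wet)
  diel_base <- act$baseline * act$nocturnal_mult^night_w *
    (1 + .acro_bump(h_mid, dawn_h, act$dawn_amp, act$acro_width_h) +
       .acro_bump(h_mid, dusk_h, act$dusk_amp, act$acro_width_h))
  mu_common <- as.vector(diel_base + slope * (w$temp - act$temp_ref_c) +
                           act$doy_trend * (doy_of(ld) - 152))

  out <- purrr::map_dfr(seq_len(cfg$n_animals), function(a) {
    mu <- mu_common + b[a]
    tibble::tibble(
      animal_id = .animal_ids(cfg)[a],
      t_hour = w$t,
      bio_day = bio_day,
      clock_hour = local_hour(w$t, off),
      doy = doy_of(bio_day),
      night = night,
      night_w = night_w,
      temp = w$temp,
      precip_mm = w$precip,
      day_dry = day_dry,
      mu_truth = mu
    )
  })
  eps <- if (act$resid_sd > 0) rnorm(nrow(out), 0, act$resid_sd) else numeric(nrow(out))
  # VeDBA sums are physically non-negative; the truncation touches only the
  # extreme hot-dry-late tail of the default world
  out$vedba_sum <- pmax(out$mu_truth + eps, 0)
  out
}

# Hann-windowed burst envelope for one hour of samples (shared across animals
# so individuals differ only in amplitude).
.burst_envelope <- function(n, rate_hz, burst_rate_per_min, dur_range_s) {
  env <- numeric(n)
  n_burst <- rpois(1, burst_rate_per_min * n / rate_hz / 60)
  if (n_burst > 0) {
    starts <- runif(n_burst, 0, n / rate_hz)
    durs <- runif(n_burst, dur_range_s[1], dur_range_s[2])
    for (k in seq_len(n_burst)) {
      i0 <- max(1L, floor(starts[k] * rate_hz))
      len <- max(2L, round(durs[k] * rate_hz))
      i1 <- min(n, i0 + len - 1L)
      idx <- i0:i1
      hann <- 0.5 - 0.5 * cos(2 * pi * (seq_along(idx) - 1) / (length(idx) - 1))
      env[idx] <- env[idx] + hann
    }
  }
  pmin(env, 1)
}

# Band-limited carrier (sum of three sinusoids in the configured band),
# normalised to unit RMS.
.carrier <- function(n, rate_hz, band_hz) {
  tt <- (seq_len(n) - 1) / rate_hz
  f <- runif(3, band_hz[1], band_hz[2])
  ph <- runif(3, 0, 2 * pi)
  x <- sin(2 * pi * f[1] * tt + ph[1]) + sin(2 * pi * f[2] * tt + ph[2]) +
    sin(2 * pi * f[3] * tt + ph[3])
  x / sqrt(mean(x^2))
}

#' Synthesize 10 Hz triaxial accelerometer streams
#'
#' Full-fidelity level, intended for spans of at most about a week. Each
#' sample is a slowly rotating gravity unit vector plus zero-mean dynamic
#' bursts (band-limited 1-3 Hz carriers under Hann envelopes) whose per-hour
#' amplitude is proportional to the hourly ground-truth intensity
#' `mu_truth` from [sim_activity_hourly()]. Burst timing is shared across
#' animals; only amplitudes differ, so individual effects are a pure scaling.
#'
#' @param config a [sim_config()].
#' @param hourly table from [sim_activity_hourly()] (any subset of its rows;
#'   streams are generated for the hours present, per animal).
#' @return tibble `animal_id`, `t` (POSIXct UTC, 0.1 s steps), `ax`, `ay`,
#'   `az` in g.
#' @export
sim_accel <- function(config, hourly) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  ac <- cfg$accel
  rate <- ac$rate_hz
  n <- as.integer(rate * 3600)
  set.seed(cfg$seed + 2L)

  hours <- sort(unique(hourly$t_hour))
  animals <- sort(unique(hourly$animal_id))
  # intensity lookup: animal x hour
  key <- paste(hourly$animal_id, as.numeric(hourly$t_hour))
  mu <- setNames(hourly$mu_truth, key)

  # slow gravity rotation: fixed low-frequency tilt/azimuth wobble
  ph_g <- runif(2, 0, 2 * pi)

  out <- vector("list", length(hours))
  for (j in seq_along(hours)) {
    h <- hours[j]
    env <- .burst_envelope(n, rate, ac$burst_rate_per_min, ac$burst_dur_s)
    cx <- .carrier(n, rate, ac$carrier_band_hz)
    cy <- .carrier(n, rate, ac$carrier_band_hz)
    cz <- .carrier(n, rate, ac$carrier_band_hz)
    tt <- as.numeric(h) + (seq_len(n) - 1) / rate
    theta <- 0.15 * sin(2 * pi * tt / 600 + ph_g[1])
    psi <- 2 * pi * tt / 1800 + ph_g[2]
    gx <- sin(theta) * cos(psi)
    gy <- sin(theta) * sin(psi)
    gz <- cos(theta)
    per_animal <- purrr::map_dfr(animals, function(a) {
      m <- mu[paste(a, as.numeric(h))]
      if (is.na(m)) return(NULL)
      # scale by the hour's envelope mass so the hourly VeDBA sum tracks the
      # intended intensity (1.7 ~ mean norm of the three unit-RMS carriers)
      env_mass <- sum(env)
      sigma <- if (env_mass > 0) m / (env_mass * 1.7) else 0
      tibble::tibble(
        animal_id = a,
        t = utc_posix(tt),
        ax = gx + sigma * env * cx,
        ay = gy + sigma * env * cy,
        az = gz + sigma * env * cz
      )
    })
    out[[j]] <- per_animal
  }
  dplyr::bind_rows(out)
}

#' Simulate GPS fixes from a biased correlated random walk
#'
#' Fixes at a regular interval around a home-range centre; displacement from
#' the centre follows an AR(1) pull in metric east/north coordinates. DOP is
#' drawn so that a configured fraction falls outside the `[1, 7]` quality
#' window (bad values land in `[0.5, 1)` or `(7, 10]`).
#'
#' @param config a [sim_config()].
#' @return tibble `animal_id`, `t`, `lat`, `lon`, `dop`.
#' @export
sim_gps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  g <- cfg$gps
  set.seed(cfg$seed + 3L)
  off <- cfg$site$tz_offset * 3600
  t0 <- utc_posix(as.POSIXct(cfg$start, tz = "UTC")) - off
  n_days <- as.integer(cfg$end - cfg$start) + 1L
  n_fix <- (n_days * 24L * 60L) %/% g$fix_interval_min
  t <- t0 + (seq_len(n_fix) - 1) * g$fix_interval_min * 60

  m_per_deg <- 111194.9
  purrr::map_dfr(.animal_ids(cfg), function(a) {
    e <- numeric(n_fix); nn <- numeric(n_fix)
    if (g$step_sd_m > 0) {
      de <- rnorm(n_fix, 0, g$step_sd_m)
      dn <- rnorm(n_fix, 0, g$step_sd_m)
      for (i in 2:n_fix) {
        e[i] <- g$attract * e[i - 1] + de[i]
        nn[i] <- g$attract * nn[i - 1] + dn[i]
      }
    } else {
      rnorm(2 * n_fix)
    }
    u <- runif(n_fix)
    dop <- ifelse(u < g$dop_bad_frac,
                  { v <- runif(n_fix, 0, 3.5); ifelse(v < 0.5, 0.5 + v, 7 + (v - 0.5) / 3 * 3) },
                  runif(n_fix, 1, 7))
    tibble::tibble(
      animal_id = a,
      t = t,
      lat = cfg$site$lat + nn / m_per_deg,
      lon = cfg$site$lon + e / (m_per_deg * cos(cfg$site$lat * pi / 180)),
      dop = dop
    )
  })
}

#' Simulate a heatwave-level modelling table with known coefficients
#'
#' Direct generator at the heatwave scale for calibrating the heatwave mixed
#' model: the response is a Gaussian linear function of z-scored mean daily
#' maximum temperature, heatwave length, precipitation presence and the two
#' interactions, plus an animal intercept.
#'
#' @param n_heatwaves,n_animals table dimensions.
#' @param beta named coefficients on the scaled predictors:
#'   `intercept`, `tmax`, `length`, `precip`, `length_precip`, `tmax_precip`.
#' @param sd_animal,sd_resid random-intercept and residual SDs.
#' @param seed RNG seed.
#' @return tibble `animal_id`, `heatwave_id`, `tmax_mean`, `length_days`,
#'   `precip_presence`, `vedba_mean`, plus the scaled covariates used.
#' @export
sim_heatwaves <- function(n_heatwaves = 30, n_animals = 10,
                          beta = c(intercept = 4000, tmax = 150, length = 0,
                                   precip = 100, length_precip = 0,
                                   tmax_precip = 0),
                          sd_animal = 300, sd_resid = 500, seed = 1L) {
  set.seed(as.integer(seed))
  tmax <- runif(n_heatwaves, 24.5, 32)
  len <- sample(1:5, n_heatwaves, replace = TRUE, prob = c(.4, .25, .18, .1, .07))
  precip <- rbinom(n_heatwaves, 1, 0.4)
  b <- rnorm(n_animals, 0, sd_animal)
  grid <- tidyr::expand_grid(animal = seq_len(n_animals), hw = seq_len(n_heatwaves))
  # z-score over the expanded animal x heatwave rows, matching how the
  # modelling table is scaled at fit time
  tz <- as.numeric(scale(tmax[grid$hw]))
  lz <- as.numeric(scale(len[grid$hw]))
  mu <- beta[["intercept"]] + beta[["tmax"]] * tz +
    beta[["length"]] * lz + beta[["precip"]] * precip[grid$hw] +
    beta[["length_precip"]] * lz * precip[grid$hw] +
    beta[["tmax_precip"]] * tz * precip[grid$hw] + b[grid$animal]
  tibble::tibble(
    animal_id = sprintf("A%02d", grid$animal),
    heatwave_id = grid$hw,
    tmax_mean = tmax[grid$hw],
    length_days = len[grid$hw],
    precip_presence = factor(ifelse(precip[grid$hw] == 1, "presence", "absence"),
                             levels = c("absence", "presence")),
    tmax_z = tz,
    length_z = lz,
    vedba_mean = mu + rnorm(nrow(grid), 0, sd_resid)
  )
}
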