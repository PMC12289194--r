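# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops / closed forms so the implementation under test
# shares no code path with its check.

# --- rolling means / VeDBA ------------------------------------------------

oracle_roll_mean <- function(x, k) {
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# full per-sample recomputation: per-axis static by loop, norm, loop smooth
oracle_vedba <- function(stream, k = 21) {
  sx <- oracle_roll_mean(stream$ax, k)
  sy <- oracle_roll_mean(stream$ay, k)
  sz <- oracle_roll_mean(stream$az, k)
  n <- nrow(stream)
  v <- numeric(n)
  for (i in seq_len(n)) {
    v[i] <- sqrt((stream$ax[i] - sx[i])^2 + (stream$ay[i] - sy[i])^2 +
                   (stream$az[i] - sz[i])^2)
  }
  list(vedba = v, vedba_smoothed = oracle_roll_mean(v, k))
}

# --- solar ----------------------------------------------------------------

# independent copy of the NOAA series, used only to scan elevations
oracle_elev <- function(lat, lon, doy, hour_utc) {
  g <- 2 * pi / 365 * (doy - 1 + (hour_utc - 12) / 24)
  eqt <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  d <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- (hour_utc * 60 + eqt + 4 * lon) %% 1440
  ha <- (tst / 4 - 180) * pi / 180
  phi <- lat * pi / 180
  cz <- sin(phi) * sin(d) + cos(phi) * cos(d) * cos(ha)
  90 - acos(pmin(1, pmax(-1, cz))) * 180 / pi
}

# minute-grid scan for the -0.833 deg crossings; returns UTC minutes of day
oracle_sun_scan <- function(lat, lon, date) {
  doy <- as.integer(format(date, "%j"))
  mins <- 0:1439
  e <- oracle_elev(lat, lon, doy, mins / 60)
  up <- e > -0.833
  if (all(up)) return(list(polar = "day"))
  if (!any(up)) return(list(polar = "night"))
  rises <- which(!up[-length(up)] & up[-1])
  sets <- which(up[-length(up)] & !up[-1])
  list(polar = "none",
       sunrise_min = if (length(rises)) mins[rises[1] + 1] else NA,
       sunset_min = if (length(sets)) mins[sets[1] + 1] else NA)
}

# linear interval scan for bio-day / phase assignment
oracle_bio_day <- function(t, solar) {
  tn <- as.numeric(t)
  out <- as.Date(rep(NA_integer_, length(t)), origin = "1970-01-01")
  for (j in seq_along(t)) {
    for (i in seq_len(nrow(solar) - 1)) {
      if (tn[j] >= as.numeric(solar$sunrise[i]) &&
          tn[j] < as.numeric(solar$sunrise[i + 1])) {
        out[j] <- solar$date[i]
        break
      }
    }
  }
  out
}

oracle_phase <- function(t, solar) {
  bd <- oracle_bio_day(t, solar)
  out <- character(length(t))
  for (j in seq_along(t)) {
    i <- which(solar$date == bd[j])
    out[j] <- if (as.numeric(t[j]) >= as.numeric(solar$sunrise[i]) &&
                  as.numeric(t[j]) < as.numeric(solar$sunset[i])) "day" else "night"
  }
  out
}

# --- heatwaves ------------------------------------------------------------

# exhaustive scan: every maximal run of consecutive qualifying days
oracle_heatwaves <- function(daily, threshold = 24, min_hours = 23) {
  daily <- daily[order(daily$bio_day), ]
  q <- daily$hours_covered >= min_hours & daily$temp_mean > threshold
  n <- nrow(daily)
  contiguous <- function(i, j) as.integer(daily$bio_day[j] - daily$bio_day[i]) == 1
  runs <- list()
  i <- 1
  while (i <= n) {
    starts_run <- q[i] && (i == 1 || !q[i - 1] || !contiguous(i - 1, i))
    if (starts_run) {
      j <- i
      while (j < n && q[j + 1] && contiguous(j, j + 1)) j <- j + 1
      runs[[length(runs) + 1]] <- list(
        start = daily$bio_day[i], end = daily$bio_day[j], len = j - i + 1,
        tmax_mean = mean(daily$temp_max[i:j]),
        precip_total = sum(daily$precip_total[i:j])
      )
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# --- movement -------------------------------------------------------------

oracle_hav <- function(lat1, lon1, lat2, lon2) {
  p <- pi / 180
  a <- sin((lat2 - lat1) * p / 2)^2 +
    cos(lat1 * p) * cos(lat2 * p) * sin((lon2 - lon1) * p / 2)^2
  2 * 6371000 * asin(sqrt(a))
}

oracle_day_metrics <- function(df, gap_cap_s = Inf) {
  n <- nrow(df)
  if (n <= 1) return(list(distance = 0, max_nsd = 0, speed = 0))
  dist <- 0; speeds <- c(); max_nsd <- 0
  for (i in seq_len(n)) {
    nsd <- oracle_hav(df$lat[1], df$lon[1], df$lat[i], df$lon[i])^2
    if (nsd > max_nsd) max_nsd <- nsd
  }
  for (i in seq_len(n - 1)) {
    dt <- as.numeric(df$t[i + 1]) - as.numeric(df$t[i])
    if (dt <= gap_cap_s) {
      s <- oracle_hav(df$lat[i], df$lon[i], df$lat[i + 1], df$lon[i + 1])
      dist <- dist + s
      speeds <- c(speeds, s / dt)
    }
  }
  list(distance = dist, max_nsd = max_nsd,
       speed = if (length(speeds)) mean(speeds) else 0)
}
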