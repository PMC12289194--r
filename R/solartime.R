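# Sunrise/sunset from the NOAA low-accuracy solar position equations and
# assignment of timestamps to sunrise-anchored biological days. A biological
# day runs from sunrise on date d to the following sunrise, so a full
# nocturnal active phase falls inside one day label.

# Fractional-year angle (radians) at a given day-of-year and fractional hour
.solar_gamma <- function(doy, hour) {
  2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
}

# Equation of time in minutes
.solar_eqtime <- function(gamma) {
  229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
              0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
}

# Solar declination in radians
.solar_decl <- function(gamma) {
  0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
}

#' Solar elevation angle
#'
#' Elevation of the sun's centre above the horizon (degrees, unrefracted) at a
#' UTC instant, from the NOAA solar-position series.
#'
#' @param lat,lon site coordinates in decimal degrees (north/east positive).
#' @param t POSIXct timestamp(s), UTC.
#' @return numeric vector of elevations in degrees.
#' @export
solar_elevation <- function(lat, lon, t) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180)
  t <- utc_posix(t)
  doy <- doy_of(as.Date(t, tz = "UTC"))
  hour <- (as.numeric(t) %% 86400) / 3600
  gamma <- .solar_gamma(doy, hour)
  eqtime <- .solar_eqtime(gamma)
  decl <- .solar_decl(gamma)
  tst <- (hour * 60 + eqtime + 4 * lon) %% 1440
  ha <- (tst / 4) - 180
  phi <- lat * pi / 180
  cos_zen <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha * pi / 180)
  cos_zen <- pmin(1, pmax(-1, cos_zen))
  90 - acos(cos_zen) * 180 / pi
}

# zenith used for rise/set: 90.833 deg = refraction (34') + solar disc (16')
.ZENITH <- 90.833

#' Sunrise and sunset for one or more dates
#'
#' NOAA sunrise equation at solar elevation -0.833 degrees (standard
#' refraction plus solar-disc correction). At polar day/night there is no
#' horizon crossing: `sunrise`/`sunset` are `NA` and `polar` records which
#' regime applies — never a silent default time.
#'
#' @param lat,lon site coordinates in decimal degrees.
#' @param dates Date vector (local calendar dates).
#' @param tz_offset fixed local UTC offset in hours.
#' @return tibble with columns `date`, `sunrise`, `sunset` (POSIXct, UTC
#'   instants; add `tz_offset` hours for clock time), `polar`
#'   (`"none"`, `"day"` or `"night"`).
#' @examples
#' solar_events(50, 14.8, as.Date("2019-06-21"), tz_offset = 2)
#' @export
solar_events <- function(lat, lon, dates, tz_offset = 0) {
  stopifnot(abs(lat) <= 90, abs(lon) <= 180)
  dates <- as.Date(dates)
  phi <- lat * pi / 180

  one_day <- function(d) {
    doy <- doy_of(d)
    # iterate: gamma at solar noon, then refine at the event estimate
    sunrise_min <- 720; sunset_min <- 720
    polar <- "none"
    for (iter in 1:3) {
      g_rise <- .solar_gamma(doy, sunrise_min / 60)
      g_set <- .solar_gamma(doy, sunset_min / 60)
      ha_of <- function(g) {
        decl <- .solar_decl(g)
        arg <- cos(.ZENITH * pi / 180) / (cos(phi) * cos(decl)) -
          tan(phi) * tan(decl)
        if (arg > 1) return(list(ha = NA_real_, polar = "night"))
        if (arg < -1) return(list(ha = NA_real_, polar = "day"))
        list(ha = acos(arg) * 180 / pi, polar = "none")
      }
      r <- ha_of(g_rise); s <- ha_of(g_set)
      if (is.na(r$ha) || is.na(s$ha)) {
        polar <- if (is.na(r$ha)) r$polar else s$polar
        return(list(sunrise = NA_real_, sunset = NA_real_, polar = polar))
      }
      sunrise_min <- 720 - 4 * (lon + r$ha) - .solar_eqtime(g_rise)
      sunset_min <- 720 - 4 * (lon - s$ha) - .solar_eqtime(g_set)
    }
    list(sunrise = sunrise_min, sunset = sunset_min, polar = "none")
  }

  res <- purrr::map(dates, one_day)
  day_start <- utc_posix(as.POSIXct(dates, tz = "UTC"))
  tibble::tibble(
    date = dates,
    sunrise = day_start + purrr::map_dbl(res, "sunrise") * 60,
    sunset = day_start + purrr::map_dbl(res, "sunset") * 60,
    polar = purrr::map_chr(res, "polar")
  )
}

#' Solar table covering a date span
#'
#' Convenience wrapper over [solar_events()] for `start - 1` to `end + 1`
#' (the padding lets every timestamp on `start..end` be bracketed by
#' sunrises).
#' @param lat,lon,tz_offset as in [solar_events()].
#' @param start,end Dates.
#' @export
solar_table <- function(lat, lon, start, end, tz_offset = 0) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start <= end)
  solar_events(lat, lon, seq(start - 1, end + 1, by = "day"), tz_offset)
}

.check_solar <- function(solar) {
  stopifnot(is.data.frame(solar),
            all(c("date", "sunrise", "sunset") %in% names(solar)))
  if (any(solar$polar != "none")) {
    stop("solar table contains polar day/night dates; biological days are undefined",
         call. = FALSE)
  }
  solar[order(solar$date), , drop = FALSE]
}

#' Assign timestamps to sunrise-anchored biological days
#'
#' Biological day `d` is the half-open interval
#' `[sunrise(d), sunrise(d + 1))`.
#'
#' @param t POSIXct timestamp(s), UTC.
#' @param solar table from [solar_table()]; must cover each timestamp's date
#'   plus the following sunrise.
#' @return Date vector of biological-day labels.
#' @export
assign_bio_day <- function(t, solar) {
  solar <- .check_solar(solar)
  t <- utc_posix(t)
  sr <- as.numeric(solar$sunrise)
  idx <- findInterval(as.numeric(t), sr)
  bad <- idx == 0L | idx >= length(sr) + 1L | as.numeric(t) >= sr[length(sr)]
  if (any(bad)) {
    missing_dates <- unique(as.Date(t[bad], tz = "UTC"))
    stop("solar table does not cover timestamp(s) on: ",
         paste(missing_dates, collapse = ", "), call. = FALSE)
  }
  solar$date[idx]
}

#' Classify timestamps as day or night within their biological day
#'
#' Day is the half-open interval `[sunrise(d), sunset(d))` of the timestamp's
#' biological day; the rest of the biological day (sunset to next sunrise) is
#' night. The boar's resting phase is the day, the active phase the night.
#'
#' @inheritParams assign_bio_day
#' @return character vector, `"day"` or `"night"`.
#' @export
day_night <- function(t, solar) {
  solar <- .check_solar(solar)
  t <- utc_posix(t)
  bd <- assign_bio_day(t, solar)
  i <- match(bd, solar$date)
  ifelse(as.numeric(t) >= as.numeric(solar$sunrise[i]) &
           as.numeric(t) < as.numeric(solar$sunset[i]), "day", "night")
}
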