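# Hourly weather intake, binary precipitation coding, and aggregation to
# biological days. Precipitation is a strict binary: any amount above 0 mm is
# "presence", exactly 0 mm is "absence" (no trace threshold).

.precip_levels <- c("absence", "presence")

#' Binary precipitation coding
#'
#' Strict coding: `presence` iff the total is greater than 0 mm.
#'
#' @param total precipitation totals in mm (non-negative).
#' @return factor with levels `absence`, `presence`.
#' @export
precip_binary <- function(total) {
  if (any(is.na(total))) stop("missing precipitation totals", call. = FALSE)
  if (any(total < 0)) stop("negative precipitation total", call. = FALSE)
  factor(ifelse(total > 0, "presence", "absence"), levels = .precip_levels)
}

.weather_check <- function(hours) {
  stopifnot(is.data.frame(hours),
            all(c("t", "temp", "precip") %in% names(hours)))
  if (any(hours$precip < 0)) stop("negative precipitation", call. = FALSE)
  if (any(hours$temp < -40 | hours$temp > 50)) {
    stop("temperature outside the [-40, 50] C sanity bounds", call. = FALSE)
  }
  hours
}

#' Aggregate hourly weather to biological days
#'
#' Hours are assigned to sunrise-anchored biological days (by the hour's
#' start timestamp) and summarised: mean and maximum temperature, total
#' precipitation, its binary presence, and the hour count actually covered.
#' `calendar_days = TRUE` instead groups by local calendar date (some
#' weather providers report calendar days).
#'
#' @param hours tibble `t`, `temp`, `precip` at hourly cadence.
#' @param solar solar table covering the span (ignored when
#'   `calendar_days = TRUE`).
#' @param tz_offset local UTC offset in hours (calendar-day mode).
#' @param calendar_days group by local calendar date instead of biological
#'   day.
#' @return tibble `bio_day`, `temp_mean`, `temp_max`, `precip_total`,
#'   `precip_presence`, `hours_covered`.
#' @export
daily_weather <- function(hours, solar = NULL, tz_offset = 0,
                          calendar_days = FALSE) {
  hours <- .weather_check(hours)
  if (calendar_days) {
    hours$bio_day <- local_date(hours$t, tz_offset)
  } else {
    if (is.null(solar)) stop("`solar` table required unless calendar_days = TRUE",
                             call. = FALSE)
    hours$bio_day <- assign_bio_day(hour_floor(hours$t), solar)
  }
  hours |>
    dplyr::group_by(.data$bio_day) |>
    dplyr::summarise(temp_mean = mean(.data$temp),
                     temp_max = max(.data$temp),
                     precip_total = sum(.data$precip),
                     hours_covered = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(precip_presence = precip_binary(.data$precip_total)) |>
    dplyr::arrange(.data$bio_day)
}

#' Join activity with weather at the matching temporal scale
#'
#' Inner join producing the modelling tables: an hourly activity table (with
#' `t_hour`) gains the hour's temperature and a per-hour precipitation
#' factor; a daily activity table (with `bio_day` only) gains the day's
#' maximum temperature and daily precipitation presence. Unmatched activity
#' rows are dropped with a message; an empty intersection is an error.
#'
#' @param activity hourly table from [hourly_summary()] or daily table from
#'   [daily_summary()].
#' @param weather hourly weather (`t`, `temp`, `precip`) for the hourly
#'   scale, or a [daily_weather()] table for the daily scale.
#' @return the activity table with weather columns appended (`temp` and
#'   `precip` factor at the hourly scale; `temp_max`, `precip_total`,
#'   `precip` factor at the daily scale).
#' @export
join_weather <- function(activity, weather) {
  if ("t_hour" %in% names(activity)) {
    stopifnot(all(c("t", "temp", "precip") %in% names(weather)))
    w <- dplyr::transmute(weather, t_hour = hour_floor(.data$t),
                          temp = .data$temp,
                          precip = precip_binary(.data$precip))
    out <- dplyr::inner_join(activity, w, by = "t_hour")
  } else {
    stopifnot("bio_day" %in% names(activity),
              all(c("bio_day", "temp_max", "precip_presence") %in% names(weather)))
    w <- dplyr::select(weather, "bio_day", "temp_max", "precip_total",
                       precip = "precip_presence")
    out <- dplyr::inner_join(activity, w, by = "bio_day")
  }
  if (nrow(out) == 0L) {
    stop("activity and weather tables share no keys", call. = FALSE)
  }
  dropped <- nrow(activity) - nrow(out)
  if (dropped > 0) {
    message(dropped, " activity row(s) dropped: no matching weather record")
  }
  out
}
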