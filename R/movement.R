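# GPS quality filtering and daily movement metrics: distance travelled,
# maximum net squared displacement (NSD, anchored at the day's first fix)
# and mean step speed, per sunrise-anchored biological day. Distances are
# great-circle (haversine) on a 6371 km sphere; over a study area a few km
# across the spherical-vs-projected difference is negligible.

.EARTH_R_M <- 6371000

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @param radius_m sphere radius in metres.
#' @return distance in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = .EARTH_R_M) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_m * asin(pmin(1, sqrt(a)))
}

#' Filter GPS fixes by dilution of precision
#'
#' Retains fixes with `1 <= dop <= 7` (both bounds inclusive); the removal
#' count is reported with a message.
#'
#' @param fixes tibble with at least a `dop` column.
#' @return the retained fixes.
#' @export
filter_dop <- function(fixes) {
  stopifnot(is.data.frame(fixes))
  if (!"dop" %in% names(fixes) || any(is.na(fixes$dop))) {
    stop("every fix needs a DOP value", call. = FALSE)
  }
  keep <- fixes$dop >= 1 & fixes$dop <= 7
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " fix(es) removed by the DOP filter (kept 1 <= DOP <= 7)")
  }
  fixes[keep, , drop = FALSE]
}

#' Daily movement metrics per biological day
#'
#' Within each (animal, biological day), for consecutive fixes:
#' distance travelled is the sum of haversine step lengths; maximum NSD is
#' the largest squared displacement from the day's first fix; mean speed is
#' the mean of step length over step duration. Steps whose duration exceeds
#' `gap_cap_min` minutes (default 4x the nominal fix interval) are excluded
#' from distance and speed — a step across a long fix outage is not a
#' travelled path — but NSD keeps all fixes since displacement needs no path.
#'
#' @param fixes filtered, per-animal sorted tibble `animal_id`, `t`, `lat`,
#'   `lon`.
#' @param solar solar table covering the fixes' span.
#' @param fix_interval_min nominal fix interval (minutes).
#' @param gap_cap_min steps longer than this are dropped from distance and
#'   speed; default `4 * fix_interval_min`.
#' @return tibble `animal_id`, `bio_day`, `distance_m`, `max_nsd_m2`,
#'   `mean_speed_ms`, `n_fixes`.
#' @export
daily_metrics <- function(fixes, solar, fix_interval_min = 30,
                          gap_cap_min = 4 * fix_interval_min) {
  stopifnot(all(c("animal_id", "t", "lat", "lon") %in% names(fixes)))
  fixes |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      assert_sorted_times(df$t, paste0("fix timestamps (", key$animal_id, ")"))
      df$bio_day <- assign_bio_day(df$t, solar)
      df |>
        dplyr::group_by(.data$bio_day) |>
        dplyr::group_modify(~.one_day_metrics(.x, gap_cap_min)) |>
        dplyr::ungroup() |>
        dplyr::mutate(doy = doy_of(.data$bio_day))
    }) |>
    dplyr::ungroup()
}

.one_day_metrics <- function(df, gap_cap_min) {
  n <- nrow(df)
  if (n <= 1L) {
    return(tibble::tibble(distance_m = 0, max_nsd_m2 = 0, mean_speed_ms = 0,
                          n_fixes = n))
  }
  step <- haversine_m(df$lat[-n], df$lon[-n], df$lat[-1], df$lon[-1])
  dt <- diff(as.numeric(df$t))
  ok <- dt <= gap_cap_min * 60
  nsd <- haversine_m(df$lat[1], df$lon[1], df$lat, df$lon)^2
  tibble::tibble(
    distance_m = sum(step[ok]),
    max_nsd_m2 = max(nsd),
    mean_speed_ms = if (any(ok)) mean(step[ok] / dt[ok]) else 0,
    n_fixes = n
  )
}
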