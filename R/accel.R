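# VeDBA from raw triaxial acceleration. The static (gravitational) component
# is a 2 s centred rolling mean per axis; the dynamic component is the raw
# signal minus the static estimate; VeDBA is the Euclidean norm of the three
# dynamic components, then smoothed with the same 2 s centred window
# ("smoothed VeDBA"). Edges use shrinking windows; gaps longer than 1 s break
# the window so smoothing never crosses a recording gap.

.accel_check <- function(stream) {
  stopifnot(is.data.frame(stream),
            all(c("t", "ax", "ay", "az") %in% names(stream)))
  if (nrow(stream) == 0L) return(stream)
  assert_sorted_times(stream$t, "accelerometer timestamps")
  rng <- range(abs(c(stream$ax, stream$ay, stream$az)))
  if (rng[2] >= 16) {
    stop("acceleration outside the +/-16 g sensor range; corrupt stream?",
         call. = FALSE)
  }
  stream
}

.window_samples <- function(stream, window_s) {
  stopifnot(window_s > 0)
  if (nrow(stream) < 2L) return(1L)
  rate <- 1 / median(diff(as.numeric(stream$t)))
  k <- max(1L, round(window_s * rate))
  if (k %% 2L == 0L) k <- k + 1L
  as.integer(k)
}

#' Static (gravitational) acceleration component
#'
#' Per-axis centred rolling mean over `window_s` seconds (21 samples at the
#' nominal 10 Hz). Edge samples average over the shrinking window that fits;
#' gaps longer than `max_gap_s` split the stream so no window spans a gap.
#'
#' @param stream tibble with `t` (POSIXct, strictly increasing), `ax`, `ay`,
#'   `az` in g.
#' @param window_s smoothing window in seconds.
#' @param max_gap_s gaps longer than this (seconds) break the window.
#' @return tibble `t`, `sx`, `sy`, `sz`.
#' @export
static_component <- function(stream, window_s = 2, max_gap_s = 1) {
  stream <- .accel_check(stream)
  if (nrow(stream) == 0L) {
    return(tibble::tibble(t = stream$t, sx = numeric(0), sy = numeric(0),
                          sz = numeric(0)))
  }
  k <- .window_samples(stream, window_s)
  tibble::tibble(
    t = stream$t,
    sx = roll_mean_gapped(stream$ax, stream$t, k, max_gap_s),
    sy = roll_mean_gapped(stream$ay, stream$t, k, max_gap_s),
    sz = roll_mean_gapped(stream$az, stream$t, k, max_gap_s)
  )
}

#' VeDBA from a triaxial stream
#'
#' Vectorial sum of dynamic body acceleration: per sample,
#' `sqrt(dx^2 + dy^2 + dz^2)` where `d` is raw minus static, followed by a
#' centred rolling mean over `window_s` ("smoothed VeDBA"). The default
#' order (norm, then smooth) is the DDMT-compatible reading of a "smoothed
#' sum of VeDBA"; `order = "smooth_abs_then_norm"` instead smooths the
#' absolute per-axis dynamic components before taking the norm.
#'
#' @inheritParams static_component
#' @param order smoothing order, see Details.
#' @return tibble `t`, `vedba`, `vedba_smoothed` (both in g, non-negative).
#' @export
vedba <- function(stream, window_s = 2, max_gap_s = 1,
                  order = c("norm_then_smooth", "smooth_abs_then_norm")) {
  order <- match.arg(order)
  stream <- .accel_check(stream)
  if (nrow(stream) == 0L) {
    return(tibble::tibble(t = stream$t, vedba = numeric(0),
                          vedba_smoothed = numeric(0)))
  }
  st <- static_component(stream, window_s, max_gap_s)
  dx <- stream$ax - st$sx
  dy <- stream$ay - st$sy
  dz <- stream$az - st$sz
  k <- .window_samples(stream, window_s)
  if (order == "norm_then_smooth") {
    v <- sqrt(dx^2 + dy^2 + dz^2)
    vs <- roll_mean_gapped(v, stream$t, k, max_gap_s)
  } else {
    mx <- roll_mean_gapped(abs(dx), stream$t, k, max_gap_s)
    my <- roll_mean_gapped(abs(dy), stream$t, k, max_gap_s)
    mz <- roll_mean_gapped(abs(dz), stream$t, k, max_gap_s)
    v <- sqrt(dx^2 + dy^2 + dz^2)
    vs <- sqrt(mx^2 + my^2 + mz^2)
  }
  tibble::tibble(t = stream$t, vedba = v, vedba_smoothed = vs)
}

#' Hourly sums of smoothed VeDBA on biological days
#'
#' Samples are binned by local clock hour; each hourly bin is labelled with
#' the biological (sunrise-anchored) day containing the bin's start. Bins
#' with sample coverage below `coverage_min` are kept in the table but
#' flagged (`coverage_ok = FALSE`) so the daily summary can exclude them.
#'
#' @param series tibble from [vedba()], optionally with an `animal_id`
#'   column (kept as a grouping key).
#' @param solar solar table from [solar_table()] covering the series' span.
#' @param tz_offset local UTC offset in hours.
#' @param rate_hz nominal sampling rate, for the expected samples per hour.
#' @param coverage_min minimum fraction of expected samples for a bin to
#'   enter daily means.
#' @return tibble `animal_id` (if present), `bio_day`, `clock_hour`,
#'   `t_hour`, `vedba_sum`, `n_samples`, `coverage`, `coverage_ok`.
#' @export
hourly_summary <- function(series, solar, tz_offset = 0, rate_hz = 10,
                           coverage_min = 0.8) {
  stopifnot(all(c("t", "vedba_smoothed") %in% names(series)))
  expected <- 3600 * rate_hz
  df <- dplyr::mutate(series,
                      t_hour = hour_floor(.data$t),
                      clock_hour = local_hour(.data$t, tz_offset))
  keys <- if ("animal_id" %in% names(df)) c("animal_id", "t_hour", "clock_hour")
          else c("t_hour", "clock_hour")
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(vedba_sum = sum(.data$vedba_smoothed),
                     n_samples = dplyr::n(), .groups = "drop")
  out$bio_day <- assign_bio_day(out$t_hour, solar)
  out$coverage <- pmin(1, out$n_samples / expected)
  out$coverage_ok <- out$coverage >= coverage_min
  dplyr::arrange(
    dplyr::relocate(out, dplyr::any_of("animal_id"), "bio_day", "clock_hour",
                    "t_hour"),
    dplyr::across(dplyr::all_of(keys))
  )
}

#' Daily mean of hourly VeDBA sums on biological days
#'
#' Averages the coverage-qualified hourly sums within each
#' (animal, biological day); days with fewer than `min_hours` qualifying
#' hours are dropped (with a message) since a half-observed day would bias
#' the daily mean.
#'
#' @param hourly table from [hourly_summary()].
#' @param min_hours minimum qualifying hours for a day to be retained.
#' @return tibble `animal_id` (if present), `bio_day`, `vedba_daily_mean`,
#'   `hours_present`, `doy`.
#' @export
daily_summary <- function(hourly, min_hours = 20) {
  stopifnot(all(c("bio_day", "vedba_sum") %in% names(hourly)))
  df <- hourly
  if ("coverage_ok" %in% names(df)) df <- dplyr::filter(df, .data$coverage_ok)
  keys <- intersect(c("animal_id", "bio_day"), names(df))
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(vedba_daily_mean = mean(.data$vedba_sum),
                     hours_present = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(doy = doy_of(.data$bio_day))
  dropped <- sum(out$hours_present < min_hours)
  if (dropped > 0) {
    message(dropped, " biological day(s) dropped: fewer than ", min_hours,
            " qualifying hours")
  }
  dplyr::filter(out, .data$hours_present >= min_hours)
}
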