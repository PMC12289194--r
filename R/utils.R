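# Internal helpers: fixed-offset local time and gap-aware rolling means.
# All timestamps in the package are POSIXct instants in UTC; "local" clock
# labels come from a fixed UTC offset (the summer study window has no DST
# transition, so a constant offset is exact).

utc_posix <- function(x) {
  as.POSIXct(x, tz = "UTC")
}

#' Local clock hour of a UTC timestamp under a fixed offset
#' @param t POSIXct (UTC).
#' @param tz_offset offset from UTC in hours (e.g. 2 for CEST).
#' @return integer hour 0-23.
#' @keywords internal
local_hour <- function(t, tz_offset) {
  as.integer(format(t + tz_offset * 3600, "%H", tz = "UTC"))
}

local_date <- function(t, tz_offset) {
  as.Date(format(t + tz_offset * 3600, "%Y-%m-%d", tz = "UTC"))
}

#' Start-of-hour UTC instant for a timestamp
#' @keywords internal
hour_floor <- function(t) {
  utc_posix(floor(as.numeric(t) / 3600) * 3600)
}

doy_of <- function(d) as.integer(format(as.Date(d), "%j"))

#' Centred rolling mean with shrinking edge windows
#'
#' Mean of `x[i - half .. i + half]` clipped to the vector bounds, so edge
#' values average over fewer points instead of being dropped. `k` is forced
#' odd. O(n) via cumulative sums.
#' @keywords internal
roll_mean_centred <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  half <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment ids that break a time series at gaps
#'
#' Consecutive samples further apart than `max_gap_s` seconds start a new
#' segment; rolling windows never cross segment boundaries.
#' @keywords internal
gap_segments <- function(t, max_gap_s = 1) {
  if (length(t) == 0L) return(integer(0))
  dt <- diff(as.numeric(t))
  cumsum(c(1L, as.integer(dt > max_gap_s)))
}

#' Gap-aware centred rolling mean
#' @keywords internal
roll_mean_gapped <- function(x, t, k, max_gap_s = 1) {
  seg <- gap_segments(t, max_gap_s)
  out <- numeric(length(x))
  for (s in unique(seg)) {
    idx <- which(seg == s)
    out[idx] <- roll_mean_centred(x[idx], k)
  }
  out
}

assert_sorted_times <- function(t, what = "timestamps") {
  if (length(t) > 1L && any(diff(as.numeric(t)) <= 0)) {
    stop(what, " must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}

# circular distance between clock hours (period 24)
hour_dist <- function(h, centre) {
  d <- abs(h - centre) %% 24
  pmin(d, 24 - d)
}
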