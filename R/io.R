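# CSV readers for the three input streams. Column names are normalised so
# exports from common sources (e.g. Visual-Crossing-style weather headers)
# load without editing.

.rename_first <- function(df, target, candidates) {
  hit <- intersect(candidates, names(df))
  if (length(hit) == 0L) {
    stop("no column for `", target, "` (looked for: ",
         paste(candidates, collapse = ", "), ")", call. = FALSE)
  }
  names(df)[names(df) == hit[1]] <- target
  df
}

.parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(utc_posix(x))
  as.POSIXct(x, tz = "UTC",
             tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
}

#' Read a raw accelerometer CSV
#'
#' Expects columns `timestamp` (ISO-8601, UTC), `ax`, `ay`, `az` in g;
#' an `animal_id` column is kept if present.
#' @param path file path.
#' @return tibble `t`, `ax`, `ay`, `az` (+ `animal_id`).
#' @export
read_accel_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- .rename_first(df, "t", c("t", "timestamp", "datetime", "time"))
  df$t <- .parse_utc(df$t)
  stopifnot(all(c("ax", "ay", "az") %in% names(df)))
  tibble::as_tibble(df[, intersect(c("animal_id", "t", "ax", "ay", "az"),
                                   names(df))])
}

#' Read an hourly weather CSV
#'
#' Tolerant of Visual-Crossing-style headers: `datetime`/`timestamp`,
#' `temp`/`temperature`, `precip`/`precipitation`.
#' @param path file path.
#' @return tibble `t`, `temp`, `precip`.
#' @export
read_weather_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- .rename_first(df, "t", c("t", "datetime", "timestamp", "time"))
  df <- .rename_first(df, "temp", c("temp", "temperature", "temp_c"))
  df <- .rename_first(df, "precip", c("precip", "precipitation", "precip_mm"))
  df$t <- .parse_utc(df$t)
  .weather_check(tibble::as_tibble(df[, c("t", "temp", "precip")]))
}

#' Read a GPS fix CSV
#'
#' Expects `timestamp`, `lat`, `lon` (WGS84 decimal degrees), `dop`;
#' `animal_id` kept if present.
#' @param path file path.
#' @return tibble `animal_id` (if present), `t`, `lat`, `lon`, `dop`.
#' @export
read_gps_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  df <- .rename_first(df, "t", c("t", "timestamp", "datetime", "time"))
  df <- .rename_first(df, "lat", c("lat", "latitude"))
  df <- .rename_first(df, "lon", c("lon", "longitude", "lng"))
  df$t <- .parse_utc(df$t)
  stopifnot("dop" %in% names(df))
  tibble::as_tibble(df[, intersect(c("animal_id", "t", "lat", "lon", "dop"),
                                   names(df))])
}
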