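# Small fixture builders shared across test files.

# regular triaxial stream at `rate_hz`, columns t/ax/ay/az
make_stream <- function(n, rate_hz = 10, ax = 0, ay = 0, az = 1,
                        t0 = as.POSIXct("2019-06-10 00:00:00", tz = "UTC")) {
  tibble::tibble(
    t = t0 + (seq_len(n) - 1) / rate_hz,
    ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n)
  )
}

# noisy random stream with a gravity baseline
random_stream <- function(n, rate_hz = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  s <- make_stream(n, rate_hz)
  s$ax <- rnorm(n, 0, sd)
  s$ay <- rnorm(n, 0, sd)
  s$az <- 1 + rnorm(n, 0, sd)
  s
}

# solar table for the default study site
site_solar <- function(start = "2019-06-01", end = "2019-08-31") {
  solar_table(49.96, 14.78, as.Date(start), as.Date(end), tz_offset = 2)
}

# daily weather table from raw vectors (contiguous days unless dates given)
make_daily <- function(temp_mean, temp_max = temp_mean + 5,
                       precip_total = 0, hours_covered = 24,
                       start = as.Date("2019-07-01"), dates = NULL) {
  n <- length(temp_mean)
  tibble::tibble(
    bio_day = if (is.null(dates)) start + seq_len(n) - 1 else dates,
    temp_mean = temp_mean,
    temp_max = rep_len(temp_max, n),
    precip_total = rep_len(precip_total, n),
    hours_covered = rep_len(hours_covered, n),
    precip_presence = precip_binary(rep_len(precip_total, n))
  )
}
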