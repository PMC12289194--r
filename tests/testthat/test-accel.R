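test_that("constant streams give constant static and zero VeDBA at any orientation", {
  for (g in list(c(0, 0, 1), c(1, 0, 0), c(0.6, -0.48, 0.64))) {
    s <- make_stream(200, ax = g[1], ay = g[2], az = g[3])
    st <- static_component(s)
    expect_equal(st$sx, rep(g[1], 200))
    expect_equal(st$sz, rep(g[3], 200))
    v <- vedba(s)
    expect_equal(v$vedba, rep(0, 200))
    expect_equal(v$vedba_smoothed, rep(0, 200))
  }
})

test_that("degenerate inputs: single sample and empty stream", {
  s1 <- make_stream(1, ax = 0.2, ay = -0.1, az = 0.9)
  st <- static_component(s1)
  expect_equal(c(st$sx, st$sy, st$sz), c(0.2, -0.1, 0.9))
  expect_equal(vedba(s1)$vedba, 0)
  s0 <- make_stream(0)
  expect_equal(nrow(vedba(s0)), 0L)
})

test_that("non-monotonic timestamps are rejected", {
  s <- make_stream(10)
  s$t[5] <- s$t[3]
  expect_error(static_component(s), "increasing")
})

test_that("static component matches the brute-force windowed mean on a sinusoid", {
  n <- 600 # 1 min at 10 Hz
  s <- make_stream(n)
  s$ax <- sin(2 * pi * 1 * (seq_len(n) - 1) / 10) # 1 Hz sinusoid
  st <- static_component(s, window_s = 2)
  expect_equal(st$sx, oracle_roll_mean(s$ax, 21), tolerance = 1e-12)
})

test_that("VeDBA equals the per-sample loop oracle on synthetic burst streams", {
  s <- random_stream(1200, seed = 7)
  v <- vedba(s)
  o <- oracle_vedba(s)
  expect_equal(v$vedba, o$vedba, tolerance = 1e-9)
  expect_equal(v$vedba_smoothed, o$vedba_smoothed, tolerance = 1e-9)
})

test_that("a single-sample dynamic spike reduces to its amplitude", {
  s <- make_stream(401)
  d <- 0.8
  s$ax[201] <- d
  v <- vedba(s)
  # exact: the 21-sample static mean absorbs d/21 of the spike
  expect_equal(v$vedba[201], d * 20 / 21, tolerance = 1e-12)
  expect_equal(v$vedba[201], d, tolerance = 0.05)
  # far from the spike nothing moves
  expect_equal(v$vedba[1:150], rep(0, 150))
})

test_that("VeDBA is invariant under axis permutations and sign flips", {
  s <- random_stream(500, seed = 3)
  v0 <- vedba(s)$vedba
  perm <- tibble::tibble(t = s$t, ax = -s$az, ay = s$ax, az = -s$ay)
  expect_equal(vedba(perm)$vedba, v0, tolerance = 1e-12)
})

test_that("adding temporally separated motion never lowers VeDBA", {
  n <- 2000
  a <- make_stream(n)
  a$ax[500:560] <- a$ax[500:560] + 0.5 * sin(1:61)
  b_extra <- numeric(n)
  b_extra[1000:1060] <- 0.4 * cos(1:61) # > 21 samples away from A's burst
  ab <- a
  ab$ay <- ab$ay + b_extra
  va <- vedba(a)$vedba
  vab <- vedba(ab)$vedba
  expect_true(all(vab - va >= -1e-12))
})

test_that("gaps longer than 1 s break the smoothing window", {
  s1 <- random_stream(300, seed = 11)
  s2 <- random_stream(300, seed = 12)
  s2$t <- s1$t[300] + 5 + (seq_len(300) - 1) / 10 # 5 s gap
  joined <- dplyr::bind_rows(s1, s2)
  v <- vedba(joined)
  expect_equal(v$vedba_smoothed, c(oracle_vedba(s1)$vedba_smoothed,
                                   oracle_vedba(s2)$vedba_smoothed),
               tolerance = 1e-12)
})

test_that("hourly sums: closed form under constant smoothed VeDBA and conservation", {
  solar <- site_solar("2019-06-10", "2019-06-12")
  t0 <- as.POSIXct("2019-06-10 08:00:00", tz = "UTC")
  n <- 2 * 36000
  series <- tibble::tibble(
    t = t0 + (seq_len(n) - 1) / 10,
    vedba = 0.05, vedba_smoothed = 0.05
  )
  h <- hourly_summary(series, solar, tz_offset = 2)
  expect_equal(nrow(h), 2L)
  expect_equal(h$vedba_sum, rep(36000 * 0.05, 2))
  expect_equal(h$coverage, c(1, 1))
  expect_identical(h$clock_hour, c(10L, 11L))
  # conservation: total of hourly sums equals total of samples
  expect_equal(sum(h$vedba_sum), sum(series$vedba_smoothed))
})

test_that("hourly sums equal a brute-force groupby on (bio_day, clock_hour)", {
  solar <- site_solar("2019-06-10", "2019-06-14")
  set.seed(5)
  # sparse irregular 3-day series at 1 Hz-ish with dropped chunks
  t0 <- as.POSIXct("2019-06-10 12:00:00", tz = "UTC")
  t <- t0 + sort(sample(0:(3 * 86400), 20000))
  series <- tibble::tibble(t = t, vedba = runif(length(t)),
                           vedba_smoothed = runif(length(t)))
  h <- hourly_summary(series, solar, tz_offset = 2, rate_hz = 1)
  key_hour <- as.POSIXct(floor(as.numeric(t) / 3600) * 3600,
                         tz = "UTC", origin = "1970-01-01")
  brute <- tapply(series$vedba_smoothed, as.numeric(key_hour), sum)
  got <- setNames(h$vedba_sum, as.numeric(h$t_hour))
  expect_equal(got[names(brute)], setNames(as.numeric(brute), names(brute)),
               tolerance = 1e-12)
  # bio-day labels agree with the linear-scan oracle on the bin starts
  expect_identical(h$bio_day, oracle_bio_day(h$t_hour, solar))
})

test_that("daily means average qualifying hours and drop short days", {
  h <- tibble::tibble(
    animal_id = "A01",
    bio_day = as.Date("2019-07-01"),
    clock_hour = 0:23,
    vedba_sum = rep(120, 24),
    coverage = 1, coverage_ok = TRUE
  )
  d <- daily_summary(h)
  expect_equal(d$vedba_daily_mean, 120)
  expect_equal(d$hours_present, 24L)
  expect_equal(d$doy, 182L)
  # a 10-hour day is excluded, with a message
  h10 <- h[1:10, ]
  h10$bio_day <- as.Date("2019-07-02")
  expect_message(d2 <- daily_summary(dplyr::bind_rows(h, h10)), "dropped")
  expect_identical(d2$bio_day, as.Date("2019-07-01"))
  # low-coverage hours never enter the mean
  h$coverage_ok[1:5] <- FALSE
  h$vedba_sum[1:5] <- 1e6
  expect_equal(daily_summary(h, min_hours = 19)$vedba_daily_mean, 120)
})

test_that("daily means equal brute-force recomputation on simulated data", {
  cfg <- sim_config(seed = 9, n_animals = 2, start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-15"))
  act <- sim_activity_hourly(cfg, sim_weather(cfg))
  d <- suppressMessages(daily_summary(act, min_hours = 20))
  for (r in sample(nrow(d), 10)) {
    rows <- act$animal_id == d$animal_id[r] & act$bio_day == d$bio_day[r]
    expect_equal(d$vedba_daily_mean[r], mean(act$vedba_sum[rows]))
    expect_equal(d$hours_present[r], sum(rows))
  }
})
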