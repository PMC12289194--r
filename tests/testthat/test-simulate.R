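short_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_animals = 2, start = as.Date("2019-06-01"),
             end = as.Date("2019-06-10"), ...)
}

test_that("identical seeds give bit-identical outputs; distinct seeds differ", {
  cfg <- short_cfg(seed = 4)
  expect_identical(sim_weather(cfg), sim_weather(cfg))
  expect_identical(sim_gps(cfg), sim_gps(cfg))
  w <- sim_weather(cfg)
  expect_identical(sim_activity_hourly(cfg, w), sim_activity_hourly(cfg, w))
  cfg2 <- short_cfg(seed = 5)
  expect_false(identical(sim_weather(cfg)$temp, sim_weather(cfg2)$temp))
})

test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(start = as.Date("2019-07-01"),
                          end = as.Date("2019-06-01")), "empty date range")
  expect_error(sim_config(precip = list(p_dry = 1.2)))
  expect_error(sim_config(temp = list(ar_sd_c = -1)))
})

test_that("noise-free temperature equals the seasonal + diel curve exactly", {
  cfg <- short_cfg(temp = list(ar_sd_c = 0, heatwaves = list()))
  w <- sim_weather(cfg)
  h <- as.integer(format(w$t + 7200, "%H", tz = "UTC"))
  doy <- as.integer(format(as.Date(w$t + 7200, tz = "UTC"), "%j"))
  expected <- 17.8 + 2.5 * cos(2 * pi * (doy - 200) / 365) +
    5.5 * cos(2 * pi * (h - 15) / 24)
  expect_equal(w$temp, expected, tolerance = 1e-12)
})

test_that("heatwave injection is additive on the injected days only", {
  cfg0 <- short_cfg(temp = list(ar_sd_c = 0, heatwaves = list()))
  cfg1 <- short_cfg(temp = list(ar_sd_c = 0, heatwaves = list(
    list(start_day = 3, length_days = 2, boost_c = 6)
  )))
  w0 <- sim_weather(cfg0); w1 <- sim_weather(cfg1)
  diffs <- w1$temp - w0$temp
  boosted <- rep(rep(c(0, 6, 0), c(2, 2, 6)), each = 24)
  expect_equal(diffs, boosted)
})

test_that("degenerate precipitation probabilities behave", {
  all_dry <- short_cfg(precip = list(p_dry = 1))
  expect_true(all(sim_weather(all_dry)$precip == 0))
  all_wet <- short_cfg(precip = list(p_dry = 0))
  wet_days <- tapply(sim_weather(all_wet)$precip,
                     rep(1:10, each = 24), sum)
  expect_true(all(wet_days > 0)) # every wet day has at least one wet hour
})

test_that("dry-day fraction converges to the configured probability", {
  cfg <- sim_config(seed = 2, n_animals = 1, start = as.Date("2000-01-01"),
                    end = as.Date("2000-01-01") + 9999,
                    temp = list(ar_sd_c = 0, heatwaves = list()))
  w <- sim_weather(cfg)
  day_tot <- tapply(w$precip, rep(seq_len(10000), each = 24), sum)
  expect_lt(abs(mean(day_tot == 0) - 0.42), 0.02)
})

test_that("flat activity world: no acrophases, multiplier 1, no slopes => flat diel profile", {
  cfg <- short_cfg(activity = list(dawn_amp = 0, dusk_amp = 0,
                                   nocturnal_mult = 1, temp_slope_dry = 0,
                                   temp_slope_wet = 0, doy_trend = 0,
                                   indiv_sd = 0, resid_sd = 0))
  act <- sim_activity_hourly(cfg, sim_weather(cfg))
  prof <- tapply(act$mu_truth, act$clock_hour, mean)
  expect_lt(max(prof) / min(prof), 1.05)
})

test_that("ground truth drives the synthesized stream: zero intensity is pure gravity", {
  cfg <- short_cfg()
  hours <- tibble::tibble(
    animal_id = "A01",
    t_hour = as.POSIXct("2019-06-01 10:00:00", tz = "UTC"),
    mu_truth = 0
  )
  st <- sim_accel(cfg, hours)
  expect_equal(nrow(st), 36000L)
  norm <- sqrt(st$ax^2 + st$ay^2 + st$az^2)
  expect_equal(norm, rep(1, 36000), tolerance = 1e-9) # unit gravity vector
  v <- vedba(st)
  expect_lt(max(v$vedba_smoothed), 0.02)
})

test_that("individual intercepts scale burst amplitudes with identical timing", {
  cfg <- sim_config(seed = 6, n_animals = 3, start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-01"))
  t_h <- as.POSIXct("2019-06-01 20:00:00", tz = "UTC")
  hours <- tibble::tibble(
    animal_id = c("A01", "A02", "G0"),
    t_hour = rep(t_h, 3),
    mu_truth = c(1000, 2500, 0)
  )
  st <- sim_accel(cfg, hours)
  g <- dplyr::filter(st, animal_id == "G0")   # zero-intensity = pure gravity
  a1 <- dplyr::filter(st, animal_id == "A01")
  a2 <- dplyr::filter(st, animal_id == "A02")
  expect_equal(a2$ax - g$ax, 2.5 * (a1$ax - g$ax), tolerance = 1e-12)
  expect_equal(a2$az - g$az, 2.5 * (a1$az - g$az), tolerance = 1e-12)
})

test_that("hourly VeDBA recovered from the 10 Hz stream tracks the intended intensity", {
  cfg <- sim_config(seed = 3, n_animals = 1, start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-03")) # 3 days: desk-scale stand-in
  w <- sim_weather(cfg)
  solar <- site_solar("2019-06-01", "2019-06-03")
  act <- sim_activity_hourly(cfg, w, solar)
  st <- sim_accel(cfg, act)
  v <- vedba(st)
  v$animal_id <- st$animal_id
  h <- hourly_summary(v, solar, tz_offset = 2)
  m <- dplyr::inner_join(h, act, by = "t_hour")
  expect_gt(nrow(m), 70)
  expect_gt(cor(m$vedba_sum.x, m$mu_truth, method = "spearman"), 0.95)
})

test_that("stationary walk and DOP extremes behave as configured", {
  cfg0 <- short_cfg(gps = list(step_sd_m = 0))
  g0 <- sim_gps(cfg0)
  expect_true(all(g0$lat == 49.96 & g0$lon == 14.78))
  solar <- site_solar("2019-06-01", "2019-06-10")
  mv <- daily_metrics(suppressMessages(filter_dop(g0)), solar)
  expect_true(all(mv$distance_m == 0 & mv$max_nsd_m2 == 0))

  cfg_good <- short_cfg(gps = list(dop_bad_frac = 0))
  gg <- sim_gps(cfg_good)
  expect_identical(nrow(filter_dop(gg)), nrow(gg))
})

test_that("injected bad-DOP fraction is removed at the configured rate", {
  cfg <- sim_config(seed = 8, n_animals = 1, start = as.Date("2019-06-01"),
                    end = as.Date("2019-09-20"), # >5000 fixes at 30 min
                    gps = list(dop_bad_frac = 0.2))
  g <- sim_gps(cfg)
  expect_gt(nrow(g), 5000)
  removed <- nrow(g) - nrow(suppressMessages(filter_dop(g)))
  p_hat <- removed / nrow(g)
  ci_half <- 4 * sqrt(0.2 * 0.8 / nrow(g))
  expect_lt(abs(p_hat - 0.2), ci_half)
})
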