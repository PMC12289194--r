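# small simulated modelling tables ----------------------------------------

hourly_table <- function(seed = 1, n_animals = 2, days = 15, ...) {
  cfg <- sim_config(seed = seed, n_animals = n_animals,
                    start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-01") + days - 1, ...)
  act <- sim_activity_hourly(cfg, sim_weather(cfg))
  dplyr::mutate(act, precip = precip_binary(precip_mm))
}

daily_table <- function(seed = 1, n_animals = 3, days = 60, ...) {
  cfg <- sim_config(seed = seed, n_animals = n_animals,
                    start = as.Date("2019-06-01"),
                    end = as.Date("2019-06-01") + days - 1, ...)
  w <- sim_weather(cfg)
  solar <- solar_table(49.96, 14.78, cfg$start, cfg$end, 2)
  act <- sim_activity_hourly(cfg, w, solar)
  da <- suppressMessages(daily_summary(act))
  suppressMessages(join_weather(da, daily_weather(w, solar)))
}

test_that("cyclic hour smooth is periodic: hour 0 and hour 24 predict identically", {
  f <- fit_gam_hourly(hourly_table(seed = 2))
  for (p in c("absence", "presence")) {
    nd0 <- data.frame(clock_hour = 0, temp = 20, precip = p)
    nd24 <- data.frame(clock_hour = 24, temp = 20, precip = p)
    expect_equal(predict_population(f, nd0), predict_population(f, nd24),
                 tolerance = 1e-8)
  }
})

test_that("adding a constant to the response shifts only the intercept", {
  tb <- hourly_table(seed = 3, days = 10)
  f1 <- fit_gam_hourly(tb)
  tb2 <- dplyr::mutate(tb, vedba_sum = vedba_sum + 5000)
  f2 <- fit_gam_hourly(tb2)
  expect_equal(coef(f2$fit)[["(Intercept)"]] - coef(f1$fit)[["(Intercept)"]],
               5000, tolerance = 1e-6)
  pe1 <- partial_effect(f1, "temp", "absence")
  pe2 <- partial_effect(f2, "temp", "absence")
  expect_equal(pe1$effect, pe2$effect, tolerance = 1e-6)
})

test_that("a constant response yields flat smooths and the constant as intercept", {
  tb <- dplyr::mutate(hourly_table(seed = 4, days = 10), vedba_sum = 4321)
  f <- suppressWarnings(fit_gam_hourly(tb))
  expect_equal(unname(coef(f$fit)[["(Intercept)"]]), 4321, tolerance = 1e-6)
  pe <- partial_effect(f, "temp", "absence")
  expect_lt(diff(range(pe$effect)), 1e-4)
  grid <- expand.grid(clock_hour = 0:23, temp = c(15, 25), precip = "absence")
  expect_equal(predict_population(f, grid), rep(4321, nrow(grid)),
               tolerance = 1e-6)
  # contrasts on a flat surface are zero
  expect_equal(percent_change(f, 16:17, 20:21, temp = 20), 0, tolerance = 0.01)
  expect_equal(night_day_elevation(f), 0, tolerance = 0.01)
})

test_that("a single precipitation level collapses the by-factor terms with a warning", {
  tb <- hourly_table(seed = 5, days = 6, precip = list(p_dry = 1))
  expect_warning(f <- fit_gam_hourly(tb), "one precipitation level")
  expect_false(f$by_precip)
  expect_s3_class(tidy(f), "tbl_df")
})

test_that("tidy/glance expose the term table and fit statistics", {
  f <- fit_gam_hourly(hourly_table(seed = 6, days = 10))
  td <- tidy(f)
  expect_true(all(c("(Intercept)", "precippresence") %in%
                    td$term[td$type == "parametric"]))
  expect_true(any(grepl("ti\\(temp,clock_hour\\)", td$term)))
  expect_true(any(grepl("s\\(animal_id\\)", td$term)))
  g <- glance(f)
  expect_true(g$converged)
  expect_equal(g$nobs, nrow(hourly_table(seed = 6, days = 10)))
  expect_true(g$adj.r.squared > 0 && g$adj.r.squared <= 1)
})

test_that("percent change reads a doubled window off the fitted surface", {
  # flat world with a clean 2x block in hours 20-21 via the truth multiplier
  tb <- hourly_table(seed = 7, days = 20,
                     activity = list(dawn_amp = 0, dusk_amp = 0,
                                     nocturnal_mult = 1, temp_slope_dry = 0,
                                     temp_slope_wet = 0, doy_trend = 0,
                                     indiv_sd = 0, resid_sd = 0.05))
  tb$vedba_sum[tb$clock_hour %in% c(20, 21)] <-
    tb$vedba_sum[tb$clock_hour %in% c(20, 21)] * 2
  f <- fit_gam_hourly(tb)
  pc <- percent_change(f, 16:17, 20:21, temp = 20)
  expect_equal(pc, 100, tolerance = 12) # smoothing rounds the block edges
})

test_that("seasonal model recovers a declining DOY trend and flat smooths on constants", {
  tb <- daily_table(seed = 8)
  f <- fit_gam_seasonal(tb)
  pe <- partial_effect(f, "doy", "absence")
  expect_lt(pe$effect[nrow(pe)], pe$effect[1]) # overall decline
  tb2 <- dplyr::mutate(tb, vedba_daily_mean = 777)
  f2 <- suppressWarnings(fit_gam_seasonal(tb2))
  expect_equal(unname(coef(f2$fit)[["(Intercept)"]]), 777, tolerance = 1e-6)
})

test_that("seasonal model accepts movement responses", {
  cfg <- sim_config(seed = 9, n_animals = 2, start = as.Date("2019-06-01"),
                    end = as.Date("2019-07-15"))
  w <- sim_weather(cfg)
  solar <- solar_table(49.96, 14.78, cfg$start, cfg$end, 2)
  mv <- daily_metrics(suppressMessages(filter_dop(sim_gps(cfg))), solar)
  tb <- suppressMessages(join_weather(mv, daily_weather(w, solar)))
  f <- fit_gam_seasonal(tb, response = "distance_m")
  expect_identical(f$response, "distance_m")
  expect_true(glance(f)$converged)
})

test_that("heatwave LMM recovers exact coefficients in the noise-free limit", {
  tb <- sim_heatwaves(n_heatwaves = 40, n_animals = 5,
                      beta = c(intercept = 4000, tmax = 300, length = -150,
                               precip = 120, length_precip = 80,
                               tmax_precip = -60),
                      sd_animal = 0, sd_resid = 0, seed = 10)
  f <- suppressWarnings(suppressMessages(fit_lmm_heatwave(tb)))
  est <- tidy(f)
  get <- function(term) unname(est$estimate[est$term == term])
  expect_equal(get("(Intercept)"), 4000, tolerance = 1e-6)
  expect_equal(get("tmax_z"), 300, tolerance = 1e-6)
  expect_equal(get("length_z"), -150, tolerance = 1e-6)
  expect_equal(get("precip_presencepresence"), 120, tolerance = 1e-6)
  expect_equal(get("length_z:precip_presencepresence"), 80, tolerance = 1e-5)
  expect_equal(get("tmax_z:precip_presencepresence"), -60, tolerance = 1e-5)
})

test_that("heatwave LMM rejects inestimable designs", {
  one_hw <- sim_heatwaves(n_heatwaves = 1, n_animals = 5, seed = 1)
  expect_error(fit_lmm_heatwave(one_hw), "two distinct heatwaves")
  one_animal <- sim_heatwaves(n_heatwaves = 10, n_animals = 1, seed = 1)
  expect_error(fit_lmm_heatwave(one_animal), "two animals")
})

test_that("Nakagawa R2 matches its variance-component definition", {
  tb <- sim_heatwaves(seed = 11)
  f <- fit_lmm_heatwave(tb)
  r2 <- r2_nakagawa(f)
  expect_true(all(r2 >= 0 & r2 <= 1))
  expect_gte(r2[["conditional"]], r2[["marginal"]])
  g <- glance(f)
  expect_equal(g$r2.marginal, r2[["marginal"]])
  # definition check from raw pieces
  vf <- var(as.numeric(predict(f$fit, re.form = NA)))
  vc <- as.data.frame(lme4::VarCorr(f$fit))
  vr <- vc$vcov[1]; ve <- vc$vcov[2]
  expect_equal(r2[["marginal"]], vf / (vf + vr + ve))
})

test_that("smooth-term p-values are calibrated under a null temperature effect", {
  # type-I error for the dry-branch temperature smooth at nominal 0.05;
  # 50 small replicates keep this inside the test budget
  hits <- 0
  for (r in 1:50) {
    tb <- hourly_table(seed = 1000 + r, n_animals = 2, days = 12,
                       activity = list(temp_slope_dry = 0, temp_slope_wet = 0))
    f <- fit_gam_hourly(tb)
    p <- summary(f$fit)$s.table["s(temp):precipabsence", "p-value"]
    hits <- hits + (p < 0.05)
  }
  expect_lte(hits, 9) # binomial upper bound for a true rate <= 0.10
})

test_that("autoplot and plot_diel return ggplot objects", {
  f <- fit_gam_hourly(hourly_table(seed = 12, days = 8))
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(plot_diel(f), "ggplot")
  fl <- fit_lmm_heatwave(sim_heatwaves(seed = 12))
  expect_s3_class(autoplot(fl), "ggplot")
})
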