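# End-to-end orchestration: simulate -> VeDBA -> solar/biological days ->
# weather join -> heatwaves -> movement -> models -> contrast report, with
# every stage's table persisted under a stage-numbered directory and a JSON
# manifest of per-stage row counts (the bookkeeping mirrors reporting sample
# sizes at every filtering step). Identical config + seed => byte-identical
# outputs.

#' Configuration for a full pipeline run
#'
#' @param out_dir output directory (created; stage subfolders inside).
#' @param sim a [sim_config()]; its seed drives every random stage.
#' @param coverage_min hourly-bin coverage threshold for daily means.
#' @param min_hours minimum qualifying hours per biological day.
#' @param hw_threshold_c,hw_min_hours heatwave definition (daily mean above
#'   the threshold, day coverage requirement).
#' @param gap_cap_min movement step-duration cap (minutes).
#' @param k,k_ti GAM basis dimensions.
#' @param accel_demo_hours length (hours) of the 10 Hz stream synthesized
#'   for one animal to exercise the accelerometer stack; the season-scale
#'   models run on the hourly-fidelity stream (a full season at 10 Hz is
#'   ~80 M samples per animal, far beyond a demo budget).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = sim_config(), coverage_min = 0.8,
                       min_hours = 20, hw_threshold_c = 24, hw_min_hours = 23,
                       gap_cap_min = NULL, k = 10, k_ti = 5,
                       accel_demo_hours = 6) {
  stopifnot(inherits(sim, "sim_config"))
  structure(list(out_dir = out_dir, sim = sim, coverage_min = coverage_min,
                 min_hours = min_hours, hw_threshold_c = hw_threshold_c,
                 hw_min_hours = hw_min_hours,
                 gap_cap_min = gap_cap_min %||% (4 * sim$gps$fix_interval_min),
                 k = k, k_ti = k_ti, accel_demo_hours = accel_demo_hours),
            class = "run_config")
}

#' Bundled demonstration run configuration
#'
#' The stock demo: three animals over the full June-August study window at
#' the default site, hourly-fidelity activity plus a short 10 Hz stream.
#'
#' @param out_dir output directory.
#' @param seed simulation seed.
#' @return a [run_config()].
#' @export
demo_run_config <- function(out_dir, seed = 1L) {
  run_config(out_dir = out_dir, sim = sim_config(seed = seed))
}

.stage <- function(name, log, expr) {
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  log(paste0("stage ", name, ": ok"))
  res
}

.write_stage <- function(df, dir, name) {
  readr::write_csv(df, file.path(dir, paste0(name, ".csv")))
  nrow(df)
}

#' Run the full analysis pipeline
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the assembled tables, fitted models,
#'   contrast summaries and the manifest (also written as
#'   `manifest.json` / `log.txt` / stage CSVs under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  sim <- cfg$sim
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log <- function(x) log_lines <<- c(log_lines, x)
  manifest <- list(seed = sim$seed, n_animals = sim$n_animals,
                   start = as.character(sim$start),
                   end = as.character(sim$end))
  sdir <- function(i, name) {
    d <- file.path(cfg$out_dir, sprintf("%02d_%s", i, name))
    dir.create(d, showWarnings = FALSE)
    d
  }

  # 1: synthetic inputs -------------------------------------------------
  d1 <- sdir(1, "simulate")
  weather <- .stage("simulate/weather", log, sim_weather(sim))
  solar <- .stage("simulate/solar", log,
                  solar_table(sim$site$lat, sim$site$lon, sim$start, sim$end,
                              sim$site$tz_offset))
  hourly_truth <- .stage("simulate/activity", log,
                         sim_activity_hourly(sim, weather, solar))
  gps <- .stage("simulate/gps", log, sim_gps(sim))
  first_animal <- hourly_truth$animal_id[1]
  t_cut <- min(hourly_truth$t_hour) + cfg$accel_demo_hours * 3600
  demo_hours <- dplyr::filter(hourly_truth,
                              .data$animal_id == first_animal,
                              .data$t_hour < t_cut)
  accel_stream <- .stage("simulate/accel", log, sim_accel(sim, demo_hours))
  manifest$weather_hours <- .write_stage(weather, d1, "weather")
  manifest$solar_days <- .write_stage(solar, d1, "solar")
  manifest$activity_hours <- .write_stage(hourly_truth, d1, "activity_hourly")
  manifest$gps_fixes <- .write_stage(gps, d1, "gps")
  manifest$accel_samples <- .write_stage(accel_stream, d1, "accel_10hz")

  # 2: VeDBA on the 10 Hz demo stream ----------------------------------
  d2 <- sdir(2, "vedba")
  vb <- .stage("vedba", log, vedba(accel_stream))
  vb$animal_id <- accel_stream$animal_id
  vb_hourly <- .stage("vedba/hourly", log,
                      hourly_summary(vb, solar, sim$site$tz_offset,
                                     rate_hz = sim$accel$rate_hz,
                                     coverage_min = cfg$coverage_min))
  manifest$vedba_hourly_rows <- .write_stage(vb_hourly, d2, "hourly_from_10hz")

  # 3: modelling tables -------------------------------------------------
  d3 <- sdir(3, "tables")
  hourly_tbl <- .stage("join/hourly", log, {
    act <- dplyr::select(hourly_truth, "animal_id", "t_hour", "bio_day",
                         "clock_hour", "vedba_sum")
    join_weather(act, weather)
  })
  daily_act <- .stage("daily_summary", log,
                      daily_summary(hourly_truth, min_hours = cfg$min_hours))
  dw <- .stage("daily_weather", log, daily_weather(weather, solar))
  daily_tbl <- .stage("join/daily", log, join_weather(daily_act, dw))
  manifest$hourly_model_rows <- .write_stage(hourly_tbl, d3, "hourly_model")
  manifest$daily_activity_rows <- .write_stage(daily_act, d3, "daily_activity")
  manifest$daily_weather_rows <- .write_stage(dw, d3, "daily_weather")
  manifest$daily_model_rows <- .write_stage(daily_tbl, d3, "daily_model")

  # 4: heatwaves ---------------------------------------------------------
  d4 <- sdir(4, "heatwaves")
  hw <- .stage("heatwaves/detect", log,
               detect_heatwaves(dw, cfg$hw_threshold_c, cfg$hw_min_hours))
  hw_tbl <- .stage("heatwaves/table", log, heatwave_table(hw, daily_act))
  manifest$heatwaves <- .write_stage(hw, d4, "heatwaves")
  manifest$heatwave_model_rows <- .write_stage(hw_tbl, d4, "heatwave_model")

  # 5: movement ----------------------------------------------------------
  d5 <- sdir(5, "movement")
  gps_kept <- .stage("movement/dop", log,
                     suppressMessages(filter_dop(gps)))
  log(paste0("DOP filter removed ", nrow(gps) - nrow(gps_kept), " of ",
             nrow(gps), " fixes"))
  mv <- .stage("movement/daily", log,
               daily_metrics(gps_kept, solar, sim$gps$fix_interval_min,
                             cfg$gap_cap_min))
  mv_tbl <- .stage("movement/join", log, join_weather(mv, dw))
  manifest$gps_kept <- nrow(gps_kept)
  manifest$movement_days <- .write_stage(mv, d5, "daily_movement")
  manifest$movement_model_rows <- .write_stage(mv_tbl, d5, "movement_model")

  # 6: models ------------------------------------------------------------
  d6 <- sdir(6, "models")
  gam1 <- .stage("models/gam1", log,
                 fit_gam_hourly(hourly_tbl, k = cfg$k, k_ti = cfg$k_ti))
  gam2 <- .stage("models/gam2", log,
                 fit_gam_seasonal(daily_tbl, k = cfg$k, k_ti = cfg$k_ti))
  mv_fits <- .stage("models/movement", log, {
    purrr::map(setNames(nm = c("distance_m", "max_nsd_m2", "mean_speed_ms")),
               function(r) fit_gam_seasonal(mv_tbl, response = r,
                                            k = cfg$k, k_ti = cfg$k_ti))
  })
  lmm <- NULL
  if (nrow(hw) >= 2 && length(unique(hw_tbl$animal_id)) >= 2 &&
      nrow(hw_tbl) >= 8) { # > 6 fixed effects, else rank deficient
    lmm <- .stage("models/heatwave_lmm", log, fit_lmm_heatwave(hw_tbl))
  } else {
    log("models/heatwave_lmm: skipped (too few heatwave observations)")
  }
  for (nm in c("gam1", "gam2")) {
    fit <- get(nm)
    readr::write_csv(tidy(fit), file.path(d6, paste0(nm, "_terms.csv")))
    readr::write_csv(glance(fit), file.path(d6, paste0(nm, "_fit.csv")))
  }
  if (!is.null(lmm)) {
    readr::write_csv(tidy(lmm), file.path(d6, "heatwave_lmm_terms.csv"))
    readr::write_csv(glance(lmm), file.path(d6, "heatwave_lmm_fit.csv"))
  }

  # 7: contrasts ---------------------------------------------------------
  d7 <- sdir(7, "report")
  contrasts <- .stage("report/contrasts", log, {
    tibble::tibble(
      contrast = c("afternoon_to_sunset_15C_dry", "afternoon_to_sunset_30C_dry",
                   "afternoon_to_sunset_15C_wet", "afternoon_to_sunset_30C_wet",
                   "night_over_day"),
      percent = c(
        percent_change(gam1, 16:17, 20:21, temp = 15, precip = "absence"),
        percent_change(gam1, 16:17, 20:21, temp = 30, precip = "absence"),
        percent_change(gam1, 16:17, 20:21, temp = 15, precip = "presence"),
        percent_change(gam1, 16:17, 20:21, temp = 30, precip = "presence"),
        night_day_elevation(gam1)
      )
    )
  })
  readr::write_csv(contrasts, file.path(d7, "contrasts.csv"))
  report <- c(
    "Diel model (GAM1): hourly VeDBA sum",
    utils::capture.output(print(gam1)),
    "",
    "Seasonal model (GAM2): daily mean VeDBA",
    utils::capture.output(print(gam2)),
    "",
    if (!is.null(lmm)) c("Heatwave model:", utils::capture.output(print(lmm)), "")
    else "Heatwave model: skipped",
    "Contrasts (percent change):",
    sprintf("  %-30s %8.1f", contrasts$contrast, contrasts$percent)
  )
  writeLines(report, file.path(d7, "fit_report.txt"))

  manifest$heatwave_lmm_fitted <- !is.null(lmm)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))

  invisible(list(weather = weather, solar = solar, hourly = hourly_tbl,
                 daily = daily_tbl, daily_weather = dw, heatwaves = hw,
                 heatwave_table = hw_tbl, movement = mv_tbl,
                 vedba_hourly = vb_hourly, gam1 = gam1, gam2 = gam2,
                 movement_fits = mv_fits, lmm = lmm, contrasts = contrasts,
                 manifest = manifest))
}
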