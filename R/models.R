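# The three model structures of the analysis, and the effect contrasts
# derived from them.
#
# GAM1 (diel scale): hourly VeDBA sum ~ s(temp) + cyclic s(hour) +
#   ti(temp, hour), every smooth split by the hour's binary precipitation
#   ("by" factor), precipitation as a linear main effect, and a random
#   animal intercept. Gaussian errors, REML.
# GAM2 (seasonal scale, also the post-hoc movement models): daily response ~
#   s(daily max temp) + s(DOY) + ti(tmax, DOY), split by daily
#   precipitation, plus its main effect and the animal intercept.
# Heatwave model: Gaussian linear mixed model of the per-animal mean daily
#   VeDBA within each heatwave on z-scored mean daily maximum temperature
#   and heatwave length, precipitation presence, and the two
#   temperature/length x precipitation interactions; animal intercept; ML.

.as_model_factors <- function(data) {
  data$animal_id <- factor(data$animal_id)
  if (!is.factor(data$precip)) data$precip <- factor(data$precip,
                                                     levels = .precip_levels)
  data$precip <- droplevels(data$precip)
  data
}

.gam_formula <- function(response, x1, x2, x2_cyclic, k, k2, k_ti, by_precip) {
  bs2 <- if (x2_cyclic) "cc" else "tp"
  if (by_precip) {
    f <- sprintf(
      "%s ~ precip + s(%s, by = precip, k = %d) + s(%s, bs = '%s', by = precip, k = %d) + ti(%s, %s, by = precip, bs = c('tp', '%s'), k = c(%d, %d)) + s(animal_id, bs = 're')",
      response, x1, k, x2, bs2, k2, x1, x2, bs2, k_ti[1], k_ti[length(k_ti)])
  } else {
    f <- sprintf(
      "%s ~ s(%s, k = %d) + s(%s, bs = '%s', k = %d) + ti(%s, %s, bs = c('tp', '%s'), k = c(%d, %d)) + s(animal_id, bs = 're')",
      response, x1, k, x2, bs2, k2, x1, x2, bs2, k_ti[1], k_ti[length(k_ti)])
  }
  stats::as.formula(f)
}

.fit_gam <- function(data, response, x1, x2, x2_cyclic, k, k2, k_ti, kind) {
  data <- .as_model_factors(data)
  stopifnot(all(c(response, x1, x2, "precip", "animal_id") %in% names(data)))
  by_precip <- nlevels(data$precip) == 2L
  if (!by_precip) {
    warning("only one precipitation level present; ",
            "factor-smooth terms collapse to plain smooths", call. = FALSE)
  }
  knots <- if (x2_cyclic) list(clock_hour = c(0, 24)) else NULL
  fml <- .gam_formula(response, x1, x2, x2_cyclic, k, k2, k_ti, by_precip)
  y <- data[[response]]
  if (var(y) <= 1e-10 * (1 + mean(y)^2)) {
    # REML cannot estimate smoothness for a zero-variance response; pin the
    # smooths flat so the fit degenerates cleanly to the constant
    warning("response is constant; smoothing parameters fixed", call. = FALSE)
    pre <- mgcv::gam(fml, data = data, knots = knots, fit = FALSE)
    fit <- mgcv::gam(fml, data = data, family = stats::gaussian(),
                     knots = knots, sp = rep(1e5, length(pre$S)))
  } else {
    fit <- mgcv::gam(fml, data = data, family = stats::gaussian(),
                     method = "REML", knots = knots)
  }
  if (!fit$converged) {
    stop("GAM did not converge (", kind, " model); inspect mgcv::gam.check",
         call. = FALSE)
  }
  structure(
    list(fit = fit, kind = kind, response = response,
         covars = c(x1, x2), by_precip = by_precip, data = data),
    class = "boar_gam"
  )
}

#' Fit the diel activity model (hourly scale)
#'
#' @param data hourly modelling table with `vedba_sum`, `temp`,
#'   `clock_hour`, `precip` (factor absence/presence for that hour) and
#'   `animal_id` — e.g. [join_weather()] on an [hourly_summary()], or
#'   [sim_activity_hourly()] output plus `precip = precip_binary(precip_mm)`.
#' @param k basis dimension of the temperature smooth.
#' @param k_hour basis dimension of the cyclic hour smooth. The default
#'   matches `k`; raise it (guided by `mgcv::gam.check`: an edf saturating
#'   `k - 1` signals an inadequate basis) when the diel profile has sharp
#'   crepuscular transitions a small basis cannot represent.
#' @param k_ti marginal basis dimension(s) of the tensor-product
#'   interaction: a single value, or `c(temperature, hour)` when the hour
#'   margin needs more resolution than the temperature margin (a
#'   multiplicative diel-by-temperature surface puts its raw-scale
#'   interaction on the same crepuscular scale as the hour main effect).
#' @return a `boar_gam` object (see [tidy()], [glance()], [autoplot()],
#'   [percent_change()], [night_day_elevation()]).
#' @export
fit_gam_hourly <- function(data, k = 10, k_hour = k, k_ti = 5) {
  .fit_gam(data, "vedba_sum", "temp", "clock_hour", x2_cyclic = TRUE,
           k = k, k2 = k_hour, k_ti = k_ti, kind = "hourly")
}

#' Fit the seasonal model (daily scale) for activity or movement responses
#'
#' @param data daily modelling table with the response, `temp_max`, `doy`,
#'   `precip` (daily presence factor) and `animal_id` — e.g.
#'   [join_weather()] on a [daily_summary()].
#' @param response column name: `vedba_daily_mean` (seasonal activity) or a
#'   movement metric (`distance_m`, `max_nsd_m2`, `mean_speed_ms`).
#' @inheritParams fit_gam_hourly
#' @return a `boar_gam` object.
#' @export
fit_gam_seasonal <- function(data, response = "vedba_daily_mean",
                             k = 10, k_ti = 5) {
  .fit_gam(data, response, "temp_max", "doy", x2_cyclic = FALSE,
           k = k, k2 = k, k_ti = k_ti, kind = "seasonal")
}

#' Fit the heatwave mixed model
#'
#' Gaussian linear mixed model (ML) of per-animal mean daily VeDBA within
#' heatwaves. Continuous covariates (mean daily maximum temperature,
#' heatwave length) are z-scored before fitting; the fixed effects are the
#' two main effects, precipitation presence, and the length x precipitation
#' and temperature x precipitation interactions; animal is a random
#' intercept.
#'
#' @param data table from [heatwave_table()] (or [sim_heatwaves()]):
#'   `vedba_mean`, `tmax_mean`, `length_days`, `precip_presence`,
#'   `animal_id`.
#' @return a `boar_lmm` object with Wald confidence intervals and Nakagawa
#'   marginal/conditional R2.
#' @export
fit_lmm_heatwave <- function(data) {
  stopifnot(all(c("vedba_mean", "tmax_mean", "length_days", "precip_presence",
                  "animal_id") %in% names(data)))
  if (length(unique(data$heatwave_id %||% seq_len(nrow(data)))) < 2 ||
      length(unique(paste(data$tmax_mean, data$length_days))) < 2) {
    stop("at least two distinct heatwaves are required; ",
         "the model is inestimable from one", call. = FALSE)
  }
  if (length(unique(data$animal_id)) < 2) {
    stop("at least two animals are required for the random intercept",
         call. = FALSE)
  }
  data$animal_id <- factor(data$animal_id)
  data$precip_presence <- factor(data$precip_presence, levels = .precip_levels)
  scaling <- list(tmax = c(mean = mean(data$tmax_mean), sd = sd(data$tmax_mean)),
                  length = c(mean = mean(data$length_days),
                             sd = sd(data$length_days)))
  data$tmax_z <- (data$tmax_mean - scaling$tmax["mean"]) / scaling$tmax["sd"]
  data$length_z <- (data$length_days - scaling$length["mean"]) /
    scaling$length["sd"]
  fit <- lme4::lmer(
    vedba_mean ~ tmax_z + length_z + precip_presence +
      tmax_z:precip_presence + length_z:precip_presence + (1 | animal_id),
    data = data, REML = FALSE
  )
  structure(list(fit = fit, data = data, scaling = scaling),
            class = "boar_lmm")
}

#' Population-level predictions from a fitted activity GAM
#'
#' Predictions with the animal random intercept set to zero (the population
#' level), on the response scale.
#'
#' @param object a `boar_gam`.
#' @param newdata data frame over the model covariates; `animal_id` may be
#'   omitted (a placeholder level is supplied, then excluded).
#' @param se_fit also return standard errors.
#' @return numeric vector, or a list with `fit` and `se` if `se_fit`.
#' @export
predict_population <- function(object, newdata, se_fit = FALSE) {
  stopifnot(inherits(object, "boar_gam"))
  if (!"animal_id" %in% names(newdata)) {
    newdata$animal_id <- factor(levels(object$data$animal_id)[1],
                                levels = levels(object$data$animal_id))
  }
  if (!is.factor(newdata$precip) && "precip" %in% names(newdata)) {
    newdata$precip <- factor(newdata$precip, levels = levels(object$data$precip))
  }
  p <- predict(object$fit, newdata = newdata, exclude = "s(animal_id)",
               se.fit = se_fit)
  if (se_fit) list(fit = as.numeric(p$fit), se = as.numeric(p$se.fit))
  else as.numeric(p)
}

#' Partial effect of one smooth term
#'
#' Centred contribution of a single smooth (optionally one precipitation
#' level's branch) over a covariate grid, via `predict(type = "terms")`.
#'
#' @param object a `boar_gam`.
#' @param var covariate name (`temp`, `clock_hour`, `temp_max`, `doy`).
#' @param precip_level `"absence"` or `"presence"` (ignored if the model
#'   has no precipitation split).
#' @param values grid values; defaults to 100 points over the observed range.
#' @return tibble `value`, `effect`.
#' @export
partial_effect <- function(object, var, precip_level = "absence",
                           values = NULL) {
  stopifnot(inherits(object, "boar_gam"), var %in% object$covars)
  data <- object$data
  if (is.null(values)) {
    values <- seq(min(data[[var]]), max(data[[var]]), length.out = 100)
  }
  nd <- data.frame(v = values)
  names(nd) <- var
  other <- setdiff(object$covars, var)
  nd[[other]] <- median(data[[other]])
  nd$precip <- factor(precip_level, levels = levels(data$precip))
  nd$animal_id <- factor(levels(data$animal_id)[1],
                         levels = levels(data$animal_id))
  tm <- predict(object$fit, newdata = nd, type = "terms")
  lab <- if (object$by_precip) {
    sprintf("s(%s):precip%s", var, precip_level)
  } else {
    sprintf("s(%s)", var)
  }
  stopifnot(lab %in% colnames(tm))
  tibble::tibble(value = values, effect = as.numeric(tm[, lab]))
}

.window_grid <- function(object, hours, temp, precip) {
  nd <- expand.grid(clock_hour = hours, temp = temp)
  nd$precip <- factor(precip, levels = levels(object$data$precip))
  nd
}

#' Percent change in predicted activity between two clock windows
#'
#' Population-level predictions are averaged over each window's hour grid at
#' a fixed temperature and precipitation level; the result is
#' `100 * (mean_b - mean_a) / mean_a` — e.g. late afternoon (16-18 h) to
#' around sunset (20-22 h).
#'
#' @param object a `boar_gam` from [fit_gam_hourly()].
#' @param window_a,window_b integer clock hours (0-23) of the two windows.
#' @param temp temperature (C) at which to evaluate.
#' @param precip `"absence"` or `"presence"`.
#' @return percent change (scalar).
#' @export
percent_change <- function(object, window_a, window_b, temp,
                           precip = "absence") {
  stopifnot(inherits(object, "boar_gam"), object$kind == "hourly")
  ma <- mean(predict_population(object, .window_grid(object, window_a, temp, precip)))
  mb <- mean(predict_population(object, .window_grid(object, window_b, temp, precip)))
  if (ma <= 0) {
    stop("window-a mean prediction is not positive; percent change undefined",
         call. = FALSE)
  }
  100 * (mb - ma) / ma
}

#' Night-over-day elevation of predicted activity
#'
#' The headline diel contrast: predicted activity averaged over the night
#' window 22:00-04:00 (hours 22, 23, 0-3, wrapping midnight) relative to the
#' day window 05:00-21:00 (hours 5-20), averaged over the observed
#' temperature distribution (decile grid) and over both precipitation levels
#' weighted by their observed frequency. Random effect at zero.
#'
#' @param object a `boar_gam` from [fit_gam_hourly()].
#' @param window_day,window_night integer hour grids of the two windows.
#' @return percent elevation of night over day (scalar).
#' @export
night_day_elevation <- function(object, window_day = 5:20,
                                window_night = c(22, 23, 0:3)) {
  stopifnot(inherits(object, "boar_gam"), object$kind == "hourly")
  temps <- unname(quantile(object$data$temp, probs = seq(0.05, 0.95, by = 0.1)))
  lev <- levels(object$data$precip)
  wts <- as.numeric(table(object$data$precip)[lev])
  wts <- wts / sum(wts)
  win_mean <- function(hours) {
    per_level <- purrr::map_dbl(lev, function(p) {
      mean(predict_population(object, .window_grid(object, hours, temps, p)))
    })
    sum(per_level * wts)
  }
  md <- win_mean(window_day)
  mn <- win_mean(window_night)
  if (md <= 0) {
    stop("day-window mean prediction is not positive; contrast undefined",
         call. = FALSE)
  }
  100 * (mn - md) / md
}

#' Nakagawa marginal and conditional R2 for the heatwave mixed model
#'
#' Marginal R2 is the variance explained by the fixed effects; conditional
#' R2 adds the random-intercept variance. Gaussian identity case:
#' `varF / (varF + varRE + varResid)` and
#' `(varF + varRE) / (varF + varRE + varResid)`.
#'
#' @param object a `boar_lmm`.
#' @return named numeric vector `c(marginal, conditional)`.
#' @export
r2_nakagawa <- function(object) {
  stopifnot(inherits(object, "boar_lmm"))
  fit <- object$fit
  var_f <- var(as.numeric(predict(fit, re.form = NA)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)])
  var_e <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_re + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}
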