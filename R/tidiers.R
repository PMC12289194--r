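# broom-style tidiers, print methods and ggplot2 autoplots for the two
# fitted-model classes.

#' @export
tidy.boar_gam <- function(x, ...) {
  s <- summary(x$fit)
  pt <- s$p.table
  parametric <- tibble::tibble(
    term = rownames(pt), type = "parametric",
    estimate = pt[, "Estimate"], std.error = pt[, "Std. Error"],
    statistic = pt[, 3], p.value = pt[, 4],
    edf = NA_real_, ref.df = NA_real_
  )
  st <- s$s.table
  smooths <- tibble::tibble(
    term = rownames(st), type = "smooth",
    estimate = NA_real_, std.error = NA_real_,
    statistic = st[, "F"], p.value = st[, "p-value"],
    edf = st[, "edf"], ref.df = st[, "Ref.df"]
  )
  dplyr::bind_rows(parametric, smooths)
}

#' @export
glance.boar_gam <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    adj.r.squared = s$r.sq,
    deviance.explained = s$dev.expl,
    reml = as.numeric(x$fit$gcv.ubre),
    nobs = s$n,
    converged = x$fit$converged
  )
}

#' @export
print.boar_gam <- function(x, ...) {
  cat("Activity GAMM (", x$kind, " scale), response: ", x$response, "\n",
      sep = "")
  cat("  Gaussian (identity), REML; random animal intercept; ",
      if (x$by_precip) "smooths split by precipitation\n" else
        "single precipitation level\n", sep = "")
  g <- glance(x)
  cat(sprintf("  n = %d, adj. R2 = %.3f, deviance explained = %.3f\n",
              g$nobs, g$adj.r.squared, g$deviance.explained))
  invisible(x)
}

#' @export
tidy.boar_lmm <- function(x, conf.level = 0.95, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, parm = "beta_", method = "Wald",
                       level = conf.level)
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    conf.low = ci[, 1],
    conf.high = ci[, 2]
  )
}

#' @export
glance.boar_lmm <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble::tibble(
    nobs = stats::nobs(x$fit),
    n_animals = length(unique(x$data$animal_id)),
    sigma = stats::sigma(x$fit),
    sd_animal = sqrt(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)][1]),
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    r2.marginal = unname(r2["marginal"]),
    r2.conditional = unname(r2["conditional"])
  )
}

#' @export
print.boar_lmm <- function(x, ...) {
  cat("Heatwave activity LMM (Gaussian, ML), z-scored covariates\n")
  g <- glance(x)
  cat(sprintf("  n = %d obs, %d animals; marginal R2 = %.3f, conditional R2 = %.3f\n",
              g$nobs, g$n_animals, g$r2.marginal, g$r2.conditional))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Partial-effect plot for a fitted activity GAM
#'
#' One panel per model covariate, showing the centred smooth contribution
#' by precipitation level.
#'
#' @param object a `boar_gam`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.boar_gam <- function(object, ...) {
  levs <- levels(object$data$precip)
  grid <- tidyr::expand_grid(var = object$covars, precip = levs)
  df <- purrr::pmap_dfr(grid, function(var, precip) {
    dplyr::mutate(partial_effect(object, var, precip),
                  covariate = var, precip = precip)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$effect,
                                   colour = .data$precip)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$covariate), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect (centred)",
                  colour = "precipitation") +
    ggplot2::theme_minimal()
}

#' Predicted diel activity curve
#'
#' Population-level predicted hourly VeDBA over the clock, at a chosen
#' temperature, by precipitation level.
#'
#' @param object a `boar_gam` from [fit_gam_hourly()].
#' @param temp temperature (C); default the observed median.
#' @return a ggplot object.
#' @export
plot_diel <- function(object, temp = NULL) {
  stopifnot(inherits(object, "boar_gam"), object$kind == "hourly")
  if (is.null(temp)) temp <- median(object$data$temp)
  df <- purrr::map_dfr(levels(object$data$precip), function(p) {
    nd <- .window_grid(object, seq(0, 23.5, by = 0.5), temp, p)
    pr <- predict_population(object, nd, se_fit = TRUE)
    dplyr::mutate(nd, fit = pr$fit, se = pr$se)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$clock_hour, y = .data$fit,
                                   colour = .data$precip,
                                   fill = .data$precip)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit - 1.96 * .data$se,
                                      ymax = .data$fit + 1.96 * .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "clock hour", y = "predicted hourly VeDBA sum",
                  colour = "precipitation", fill = "precipitation") +
    ggplot2::theme_minimal()
}

#' Coefficient plot for the heatwave mixed model
#'
#' @param object a `boar_lmm`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.boar_lmm <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "estimate (95% Wald CI)", y = NULL) +
    ggplot2::theme_minimal()
}
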