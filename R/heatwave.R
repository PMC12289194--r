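# Heatwave detection. A day qualifies when its biological-day mean
# temperature strictly exceeds the threshold (default 24 C, the upper bound
# of the wild boar summer thermoneutral zone) AND at least `min_hours`
# (default 23) hourly records cover the day; a heatwave is a maximal run of
# consecutive qualifying days, single-day runs included. Lengths are in days.

#' Detect heatwaves in a daily weather table
#'
#' @param daily table from [daily_weather()] (`bio_day`, `temp_mean`,
#'   `temp_max`, `precip_total`, `hours_covered`).
#' @param threshold_c daily mean temperature must strictly exceed this (C).
#' @param min_hours minimum hourly records for a day to qualify (the "23+ h"
#'   data-coverage reading; a day with patchy weather coverage cannot
#'   certify a heatwave day).
#' @return tibble, one row per heatwave: `start_day`, `end_day`,
#'   `length_days`, `tmax_mean` (mean of the constituent days' maxima),
#'   `precip_total`, `precip_presence` (over the whole period).
#' @export
detect_heatwaves <- function(daily, threshold_c = 24, min_hours = 23) {
  stopifnot(all(c("bio_day", "temp_mean", "temp_max", "precip_total",
                  "hours_covered") %in% names(daily)))
  daily <- dplyr::arrange(daily, .data$bio_day)
  if (nrow(daily) == 0L) return(.empty_heatwaves())

  gaps <- c(0, diff(as.integer(daily$bio_day)) > 1)
  n_gaps <- sum(gaps)
  if (n_gaps > 0) {
    message(n_gaps, " gap(s) in the daily series; runs split at gaps")
  }
  chunk <- cumsum(gaps)
  qualifies <- daily$hours_covered >= min_hours & daily$temp_mean > threshold_c

  out <- list()
  for (ch in unique(chunk)) {
    idx <- which(chunk == ch)
    r <- rle(qualifies[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      run <- idx[starts[j]:ends[j]]
      out[[length(out) + 1]] <- tibble::tibble(
        start_day = daily$bio_day[run[1]],
        end_day = daily$bio_day[run[length(run)]],
        length_days = length(run),
        tmax_mean = mean(daily$temp_max[run]),
        precip_total = sum(daily$precip_total[run])
      )
    }
  }
  if (length(out) == 0L) return(.empty_heatwaves())
  res <- dplyr::bind_rows(out)
  res$precip_presence <- precip_binary(res$precip_total)
  res
}

.empty_heatwaves <- function() {
  tibble::tibble(start_day = as.Date(character()),
                 end_day = as.Date(character()),
                 length_days = integer(),
                 tmax_mean = numeric(),
                 precip_total = numeric(),
                 precip_presence = factor(character(), levels = .precip_levels))
}

#' Build the heatwave-level modelling table
#'
#' One row per animal x heatwave: the response is the mean of that animal's
#' daily VeDBA means over the heatwave days; covariates are the period's
#' mean daily maximum temperature, length in days, and binary precipitation
#' presence over the whole period. Animals with no activity inside a period
#' are omitted.
#'
#' @param heatwaves table from [detect_heatwaves()].
#' @param daily_activity table from [daily_summary()] (per animal).
#' @return tibble `animal_id`, `heatwave_id`, `start_day`, `length_days`,
#'   `tmax_mean`, `precip_presence`, `vedba_mean`, `n_days_activity`.
#' @export
heatwave_table <- function(heatwaves, daily_activity) {
  stopifnot(all(c("animal_id", "bio_day", "vedba_daily_mean") %in%
                  names(daily_activity)))
  if (nrow(heatwaves) == 0L) {
    return(tibble::tibble(animal_id = character(), heatwave_id = integer(),
                          start_day = as.Date(character()),
                          length_days = integer(), tmax_mean = numeric(),
                          precip_presence = factor(character(),
                                                   levels = .precip_levels),
                          vedba_mean = numeric(), n_days_activity = integer()))
  }
  purrr::map_dfr(seq_len(nrow(heatwaves)), function(i) {
    hw <- heatwaves[i, ]
    act <- dplyr::filter(daily_activity,
                         .data$bio_day >= hw$start_day,
                         .data$bio_day <= hw$end_day)
    if (nrow(act) == 0L) return(NULL)
    act |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::summarise(vedba_mean = mean(.data$vedba_daily_mean),
                       n_days_activity = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(heatwave_id = i, start_day = hw$start_day,
                    length_days = hw$length_days, tmax_mean = hw$tmax_mean,
                    precip_presence = hw$precip_presence) |>
      dplyr::relocate("animal_id", "heatwave_id", "start_day", "length_days",
                      "tmax_mean", "precip_presence", "vedba_mean")
  })
}
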