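TRIAL_SITES <- c("chest", "arm", "thigh", "leg")
TSK_WEIGHTS <- c(chest = 0.3, arm = 0.3, thigh = 0.2, leg = 0.2)

#' Weighted-mean skin temperature
#'
#' Four-site convex combination with weights 0.3 (chest), 0.3 (arm), 0.2
#' (thigh), 0.2 (leg); vectorized over aligned series.
#'
#' @param chest,arm,thigh,leg Site temperatures, degC.
#' @return Weighted-mean skin temperature, degC.
#' @export
#' @examples
#' weighted_mean_tsk(34, 33, 32, 31)  # 32.7
weighted_mean_tsk <- function(chest, arm, thigh, leg) {
  vals <- list(chest = chest, arm = arm, thigh = thigh, leg = leg)
  if (any(purrr::map_lgl(vals, \(v) any(!is.finite(v))))) {
    abort("All four site temperatures are required (no reweighting fallback).",
          class = "thermoskin_validation_error")
  }
  0.3 * chest + 0.3 * arm + 0.2 * thigh + 0.2 * leg
}

#' Human-trial protocol phases
#'
#' Baseline seated rest, transition, three fixed-load cycling blocks
#' (moderate, moderate, light warm-down), transition, and recovery rest.
#'
#' @return A tibble: `phase`, `start_min`, `end_min`.
#' @export
trial_protocol <- function() {
  out <- tibble::tibble(
    phase = c("rest", "transition1", "FL1", "FL2", "FL3", "transition2",
              "recovery"),
    start_min = c(0, 40, 45, 60, 75, 90, 95),
    end_min = c(40, 45, 60, 75, 90, 95, 135))
  validate_periods(out$start_min, out$end_min)
  out
}

validate_periods <- function(start, end) {
  if (any(end <= start) || is.unsorted(start) ||
      any(head(end, -1) > tail(start, -1) + 1e-9)) {
    abort("Periods must be ordered and non-overlapping.",
          class = "thermoskin_validation_error")
  }
  invisible(TRUE)
}

#' Summary periods of the human trial
#'
#' The seven 3-min summary periods: end of baseline rest (BR, mins 36-39),
#' the pre-sweating fixed-load period (FL1-PS, the 3 min immediately
#' preceding the participant's sweat onset), end of each fixed-load block
#' (FL1, FL2, FL3), and mid and end of recovery rest (RR-M, RR-E).
#'
#' @param sweat_onset_min Absolute trial time of the participant's sweat
#'   onset, min (NA drops FL1-PS).
#'
#' @return A tibble: `period`, `start_min`, `end_min` (half-open windows).
#' @export
trial_periods <- function(sweat_onset_min = NA) {
  out <- tibble::tibble(
    period = c("BR", "FL1-PS", "FL1", "FL2", "FL3", "RR-M", "RR-E"),
    start_min = c(36, sweat_onset_min - 3, 57, 72, 87, 112, 131),
    end_min = c(39, sweat_onset_min, 60, 75, 90, 115, 134))
  if (is.na(sweat_onset_min)) out <- out[out$period != "FL1-PS", ]
  out
}

#' Period means of a time series
#'
#' Arithmetic mean over each half-open period window `[start_min, end_min)`.
#'
#' @param series A data frame with columns `time_min` and `value`.
#' @param periods A data frame with columns `period`, `start_min`, `end_min`.
#'
#' @return A tibble `period`, `mean`, `n`, in the order of `periods`.
#' @export
period_means <- function(series, periods) {
  purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    p <- periods[i, ]
    inside <- series$time_min >= p$start_min & series$time_min < p$end_min
    if (p$start_min < min(series$time_min) ||
        p$end_min > max(series$time_min) + 1e-9 || !any(inside)) {
      abort(sprintf("Period %s [%0.1f, %0.1f) lies outside the recording.",
                    p$period, p$start_min, p$end_min),
            class = "thermoskin_period_error")
    }
    tibble::tibble(period = p$period, mean = mean(series$value[inside]),
                   n = sum(inside))
  })
}

#' Absolute vapor pressure from temperature and relative humidity
#'
#' Magnus-form saturation vapor pressure,
#' `e_s(T) = 0.61094 * exp(17.625 T / (T + 243.04))` kPa, scaled by the
#' relative humidity: `e = (rh / 100) * e_s(T)`.  Strictly increasing in both
#' arguments.
#'
#' @param temp Air/skin temperature, degC.
#' @param rh Relative humidity, % in `[0, 100]`.
#' @return Absolute vapor pressure, kPa.
#' @export
#' @examples
#' vapor_pressure(30, 50)
vapor_pressure <- function(temp, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 100)) {
    abort("`rh` must lie in [0, 100].", class = "thermoskin_validation_error")
  }
  (rh / 100) * 0.61094 * exp(17.625 * temp / (temp + 243.04))
}

#' Detect the onset of sweating from skin vapor pressure
#'
#' For each site, the baseline is the mean absolute vapor pressure over the
#' final `baseline_min` minutes before exercise start; the site onset is the
#' first sample after exercise start at which the vapor pressure exceeds the
#' baseline by more than `threshold_kpa`, sustained for at least `sustain_s`
#' seconds.  The overall onset is the earliest site.
#'
#' @param vp A data frame with columns `site`, `time_min`, `vp` (kPa, 10-s
#'   sampling).
#' @param exercise_start_min Trial time at which exercise begins, min
#'   (>= `baseline_min` minutes of pre-exercise data are required per site).
#' @param threshold_kpa Rise above baseline defining a distinct increase, kPa.
#' @param sustain_s Minimum duration of the exceedance, s.
#' @param baseline_min Pre-exercise baseline window, min.
#'
#' @return A one-row tibble `onset_min` (minutes after exercise start),
#'   `time_min` (absolute trial time) and `site`, or a zero-row tibble when no
#'   site shows a sustained rise.
#' @export
detect_sweat_onset <- function(vp, exercise_start_min,
                               threshold_kpa = 0.5, sustain_s = 60,
                               baseline_min = 3) {
  onsets <- vp |>
    dplyr::group_by(.data$site) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$time_min)
      pre <- df$time_min >= exercise_start_min - baseline_min &
        df$time_min < exercise_start_min
      if (sum(pre) < 2) {
        abort(sprintf("Site %s has less than %g min of pre-exercise data.",
                      key$site, baseline_min),
              class = "thermoskin_validation_error")
      }
      baseline <- mean(df$vp[pre])
      post <- df[df$time_min > exercise_start_min, ]
      exceed <- post$vp - baseline > threshold_kpa
      dt_min <- diff(post$time_min)[1]
      need <- max(1L, as.integer(ceiling(sustain_s / (dt_min * 60))))
      # first index where the exceedance persists for `need` samples
      run <- rle(exceed)
      idx_end <- cumsum(run$lengths)
      hit <- which(run$values & run$lengths >= need)
      if (!length(hit)) return(NULL)
      i0 <- idx_end[hit[1]] - run$lengths[hit[1]] + 1
      tibble::tibble(site = key$site, time_min = post$time_min[i0])
    }) |>
    dplyr::bind_rows()
  if (!nrow(onsets)) {
    return(tibble::tibble(onset_min = numeric(), time_min = numeric(),
                          site = character()))
  }
  best <- onsets[which.min(onsets$time_min), ]
  tibble::tibble(onset_min = best$time_min - exercise_start_min,
                 time_min = best$time_min, site = best$site)
}

#' Within-participant inter-sensor differences from a human trial
#'
#' Per participant and period, forms the differences of weighted-mean skin
#' temperature between sensor types (Grant - custom, iButton - custom,
#' iButton - Grant) and summarizes them as group means with unadjusted 95%
#' t-intervals (df = n - 1).  Negative means indicate the first-listed sensor
#' reading cooler.  Participants missing a sensor type are excluded with a
#' warning.
#'
#' @param values A tibble with columns `participant`, `sensor_type`,
#'   `period`, `value` (weighted-mean skin temperature per period, degC).
#' @param level Confidence level.
#'
#' @return A tibble: `pair`, `period`, `mean`, `ci_low`, `ci_high`, `n`.
#' @export
trial_intersensor_differences <- function(values, level = 0.95) {
  complete <- values |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$sensor_type) == 3,
                     .groups = "drop")
  if (any(!complete$ok)) {
    warn(paste0("Excluding participant(s) missing a sensor type: ",
                paste(complete$participant[!complete$ok], collapse = ", ")),
         class = "thermoskin_participant_excluded")
    values <- dplyr::semi_join(values,
                               dplyr::filter(complete, .data$ok),
                               by = "participant")
  }
  purrr::map_dfr(INTERSENSOR_PAIRS, function(pr) {
    wide <- values |>
      dplyr::filter(.data$sensor_type %in% pr) |>
      tidyr::pivot_wider(names_from = "sensor_type", values_from = "value")
    wide |>
      dplyr::group_by(.data$period) |>
      dplyr::reframe(summarize_mean_ci(.data[[pr[1]]] - .data[[pr[2]]],
                                       level = level)) |>
      dplyr::mutate(pair = paste0(pr[1], "-", pr[2]), .before = 1)
  })
}
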