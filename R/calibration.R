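#' Identify steady-state windows in a reference series
#'
#' Scans a uniformly sampled reference temperature series for 8-min windows in
#' which the reference standard deviation is below `sd_tol` (0.007 degC for
#' the precision reference).  Selection is greedy earliest-first among
#' qualifying windows, windows never overlap, and at most one window is kept
#' per temperature plateau, plateaus being separated by more than
#' `plateau_sep` degC in reference mean.
#'
#' @param series A data frame with columns `time_s` and `value` (uniform
#'   sampling; the standard reference logs every 5 s).
#' @param window_s Window length, s.
#' @param sd_tol Maximum reference SD within a window, degC.
#' @param plateau_sep Minimum difference in window mean for a new plateau,
#'   degC.
#'
#' @return A tibble with one row per accepted window: `window_id`, `start_s`,
#'   `end_s` (half-open), `reference_mean`, `reference_sd`, `n`.  A series
#'   shorter than one window yields zero rows.
#' @export
#' @examples
#' s <- tibble::tibble(time_s = seq(0, 1195, by = 5), value = 25)
#' find_steady_windows(s)
find_steady_windows <- function(series, window_s = 480, sd_tol = 0.007,
                                plateau_sep = 0.5) {
  stopifnot(all(c("time_s", "value") %in% names(series)))
  t <- series$time_s
  x <- series$value
  n <- length(x)
  if (n < 2) return(empty_windows())
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9)) {
    abort("`series` must be uniformly sampled.",
          class = "thermoskin_validation_error")
  }
  dt <- dt[1]
  w <- as.integer(round(window_s / dt))
  if (w < 2 || n < w) return(empty_windows())

  xc <- x - mean(x)  # center for numerically stable rolling moments
  cs <- c(0, cumsum(xc))
  cs2 <- c(0, cumsum(xc^2))
  starts <- seq_len(n - w + 1)
  sums <- cs[starts + w] - cs[starts]
  sq <- cs2[starts + w] - cs2[starts]
  mu <- sums / w
  v <- pmax(0, (sq - w * mu^2) / (w - 1))
  win_sd <- sqrt(v)
  win_mean <- mu + mean(x)

  accepted <- integer(0)
  acc_means <- numeric(0)
  last_end <- -Inf
  for (i in starts) {
    if (win_sd[i] >= sd_tol) next
    if (t[i] < last_end) next
    if (length(acc_means) && min(abs(win_mean[i] - acc_means)) <= plateau_sep) next
    accepted <- c(accepted, i)
    acc_means <- c(acc_means, win_mean[i])
    last_end <- t[i] + window_s
  }
  if (!length(accepted)) return(empty_windows())
  tibble::tibble(window_id = seq_along(accepted),
                 start_s = t[accepted],
                 end_s = t[accepted] + window_s,
                 reference_mean = win_mean[accepted],
                 reference_sd = win_sd[accepted],
                 n = w)
}

empty_windows <- function() {
  tibble::tibble(window_id = integer(), start_s = numeric(),
                 end_s = numeric(), reference_mean = numeric(),
                 reference_sd = numeric(), n = integer())
}

#' Per-sensor means within steady-state windows
#'
#' @param sensors A long tibble with columns `time_s`, `sensor_id`, `value`
#'   (as in the `sensors` element of [simulate_calibration_run()]).
#' @param windows Output of [find_steady_windows()].
#'
#' @return A tibble: `window_id`, `sensor_id`, `mean`, `sd`, `n`.
#' @export
window_sensor_means <- function(sensors, windows) {
  purrr::map_dfr(seq_len(nrow(windows)), function(i) {
    win <- windows[i, ]
    sensors |>
      dplyr::filter(.data$time_s >= win$start_s, .data$time_s < win$end_s) |>
      dplyr::group_by(.data$sensor_id) |>
      dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(window_id = win$window_id, .before = 1)
  })
}

#' Fit a per-sensor linear calibration correction
#'
#' Ordinary least squares of the reference window means on the raw sensor
#' window means.  The fitted line `reference = b0 + b1 * raw` is inverted into
#' the instrument model `raw = gain * true + offset`, so the correction
#' `(raw - offset) / gain` maps raw readings onto the reference scale.
#'
#' @param reference Reference window means, degC (>= 2 values; the standard
#'   procedure uses ~5 degC steps spanning 15-40 degC).
#' @param raw Matching raw sensor window means, degC.
#' @param sensor_id Identifier stored with the fit.
#'
#' @return An object of class `sensor_cal` with fields `sensor_id`, `gain`,
#'   `offset`, `residual_sd`, `n_windows`, `span`.
#' @export
#' @examples
#' true <- c(15, 20, 25, 30, 35, 40)
#' fit <- fit_calibration(true, 1.02 * true + 0.5)
#' c(fit$gain, fit$offset)
fit_calibration <- function(reference, raw, sensor_id = "sensor") {
  if (length(reference) != length(raw)) {
    abort("`reference` and `raw` must have the same length.",
          class = "thermoskin_validation_error")
  }
  if (length(reference) < 2) {
    abort("At least 2 steady-state windows are required to fit a calibration.",
          class = "thermoskin_insufficient_data")
  }
  if (sd(raw) == 0) {
    abort("Zero variance in sensor means: degenerate calibration fit.",
          class = "thermoskin_degenerate_fit")
  }
  span <- diff(range(reference))
  if (span < 10) {
    warn(sprintf("Calibration windows span only %.1f degC (< 10 degC).", span),
         class = "thermoskin_span_warning")
  }
  fit <- lm(reference ~ raw)
  b <- coef(fit)
  if (b[[2]] <= 0) {
    abort("Non-positive fitted slope: not a physical sensor response.",
          class = "thermoskin_degenerate_fit")
  }
  structure(list(sensor_id = sensor_id,
                 gain = 1 / b[[2]],
                 offset = -b[[1]] / b[[2]],
                 residual_sd = unname(suppressWarnings(summary(fit))$sigma),
                 n_windows = length(reference),
                 span = span),
            class = "sensor_cal")
}

#' @export
print.sensor_cal <- function(x, ...) {
  cat(sprintf("<sensor_cal %s>  gain = %.5f, offset = %.4f degC (%d windows, residual SD %.4f)\n",
              x$sensor_id, x$gain, x$offset, x$n_windows, x$residual_sd))
  invisible(x)
}

#' @export
tidy.sensor_cal <- function(x, ...) {
  tibble::tibble(sensor_id = x$sensor_id,
                 term = c("gain", "offset"),
                 estimate = c(x$gain, x$offset))
}

#' @export
glance.sensor_cal <- function(x, ...) {
  tibble::tibble(sensor_id = x$sensor_id, gain = x$gain, offset = x$offset,
                 residual_sd = x$residual_sd, n_windows = x$n_windows,
                 span = x$span)
}

#' Apply a calibration correction to raw readings
#'
#' @param x Raw sensor readings, degC.
#' @param fit A `sensor_cal` from [fit_calibration()].
#'
#' @return Corrected readings `(x - offset) / gain` on the reference scale.
#' @export
apply_calibration <- function(x, fit) {
  stopifnot(inherits(fit, "sensor_cal"))
  (x - fit$offset) / fit$gain
}

#' Calibrate every sensor in a calibration run
#'
#' Finds reference steady-state windows, computes per-sensor window means, and
#' fits one linear correction per sensor.
#'
#' @param cal_run A [simulate_calibration_run()] result, or any list with
#'   `reference` and `sensors` elements in the same layout.
#' @param ... Passed to [find_steady_windows()].
#'
#' @return A tibble with one row per sensor ([glance()] of each fit) and the
#'   fit objects in a `fit` list-column.
#' @export
calibrate_sensors <- function(cal_run, ...) {
  windows <- find_steady_windows(cal_run$reference, ...)
  if (nrow(windows) < 2) {
    abort("Fewer than 2 steady-state windows found in the reference series.",
          class = "thermoskin_insufficient_data")
  }
  means <- window_sensor_means(cal_run$sensors, windows)
  means |>
    dplyr::left_join(dplyr::select(windows, "window_id", "reference_mean"),
                     by = "window_id") |>
    dplyr::group_by(.data$sensor_id) |>
    dplyr::group_map(function(df, key) {
      fit <- fit_calibration(df$reference_mean, df$mean, key$sensor_id)
      dplyr::mutate(glance(fit), fit = list(fit))
    }) |>
    dplyr::bind_rows()
}
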