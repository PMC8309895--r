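#' Fit an individual sensor against the undisturbed reference
#'
#' Ordinary least squares of the matched undisturbed reference temperature on
#' the sensor's steady-state readings, `Y' = b0 + b1 * X`, one fit per
#' individual sensor per air velocity.  Fits with R^2 at or below 0.99 (the
#' quality bar observed for well-behaved sensors on the rig) are flagged.
#'
#' @param x Sensor steady-state temperatures, degC (>= 3 paired states).
#' @param y Matched undisturbed reference temperatures, degC.
#' @param sensor_id Identifier stored with the fit.
#'
#' @return An object of class `sensor_ref_fit` with fields `sensor_id`, `b0`,
#'   `b1`, `r_squared`, `typical_error` (residual SD of the fit, degC), `n`,
#'   `flag_low_r2`.
#' @export
#' @examples
#' f <- fit_sensor_to_reference(c(24, 28, 32, 36, 40),
#'                              2 + 1.1 * c(24, 28, 32, 36, 40))
#' c(f$b0, f$b1)
fit_sensor_to_reference <- function(x, y, sensor_id = "sensor") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    abort("At least 3 paired steady states are required.",
          class = "thermoskin_insufficient_data")
  }
  if (sd(x) == 0) {
    abort("Zero variance in sensor temperatures: degenerate fit.",
          class = "thermoskin_degenerate_fit")
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits are legitimate here
  r2 <- sm$r.squared
  structure(list(sensor_id = sensor_id,
                 b0 = unname(coef(fit)[1]),
                 b1 = unname(coef(fit)[2]),
                 r_squared = r2,
                 typical_error = unname(sm$sigma),
                 n = length(x),
                 flag_low_r2 = r2 <= 0.99),
            class = "sensor_ref_fit")
}

#' @export
print.sensor_ref_fit <- function(x, ...) {
  cat(sprintf("<sensor_ref_fit %s>  Y' = %.4f + %.5f X  (R^2 = %.6f, n = %d)\n",
              x$sensor_id, x$b0, x$b1, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.sensor_ref_fit <- function(x, ...) {
  tibble::tibble(sensor_id = x$sensor_id, term = c("b0", "b1"),
                 estimate = c(x$b0, x$b1))
}

#' @export
glance.sensor_ref_fit <- function(x, ...) {
  tibble::tibble(sensor_id = x$sensor_id, b0 = x$b0, b1 = x$b1,
                 r_squared = x$r_squared, typical_error = x$typical_error,
                 n = x$n, flag_low_r2 = x$flag_low_r2)
}

#' Predict the reference temperature from a sensor reading
#'
#' @param fit A `sensor_ref_fit`.
#' @param x Sensor temperature(s), degC.
#' @return `b0 + b1 * x`, degC.
#' @export
predict_reference <- function(fit, x) {
  stopifnot(inherits(fit, "sensor_ref_fit"))
  fit$b0 + fit$b1 * x
}

#' Inverse prediction of the sensor temperature at a reference value
#'
#' Exact algebraic inversion of the sensor-to-reference line:
#' `X' = (Y' - b0) / b1`.
#'
#' @param fit A `sensor_ref_fit` (or any list with `b0`, `b1`).
#' @param y_prime Target reference temperature(s), degC.
#' @return Sensor temperature estimate(s) `X'`, degC.
#' @export
#' @examples
#' f <- list(b0 = -2, b1 = 1.05)
#' inverse_predict(f, 32)  # 32.380952...
inverse_predict <- function(fit, y_prime) {
  if (is.null(fit$b1) || fit$b1 == 0) {
    abort("Slope b1 = 0: the fit is not invertible.",
          class = "thermoskin_non_invertible")
  }
  (y_prime - fit$b0) / fit$b1
}

#' Reference fits for every sensor-bearing run of a design
#'
#' One fit per coverage x velocity x replicate (each replicate is a distinct
#' physical sensor), of the matched undisturbed reference on the sensor
#' steady-state readings across the five steps.
#'
#' @param paired Paired steady states from [match_undisturbed()].
#'
#' @return A tibble with one row per fit: identifiers, `b0`, `b1`,
#'   `r_squared`, `typical_error`, `n`, `flag_low_r2`, and the fit object in
#'   a `fit` list-column.
#' @export
sensor_reference_fits <- function(paired) {
  paired |>
    dplyr::filter(!is.na(.data$t_sen)) |>
    dplyr::group_by(.data$coverage, .data$velocity, .data$replicate) |>
    dplyr::group_map(function(df, key) {
      id <- sprintf("%s_v%02.0f_r%d", key$coverage, 100 * key$velocity,
                    key$replicate)
      fit <- fit_sensor_to_reference(df$t_sen, df$t_u, id)
      dplyr::bind_cols(key, glance(fit)[-1], tibble::tibble(fit = list(fit)))
    }) |>
    dplyr::bind_rows()
}

#' Reference-temperature anchors for the comparison periods
#'
#' Converts the custom-thermistor group means of the seven trial summary
#' periods into model reference-temperature anchors `Y'_1..7` via the
#' custom-sensor reference fits; with several custom fits, the anchor is the
#' mean of the per-sensor predictions.
#'
#' @param custom_means A tibble with columns `period` and `mean` (the seven
#'   custom-thermistor group-mean temperatures, degC), or a named numeric
#'   vector.
#' @param custom_fits A list of `sensor_ref_fit` objects for the custom
#'   sensors (or a tibble with a `fit` list-column).
#'
#' @return A tibble `period`, `y_prime` preserving the input period order.
#' @export
compute_anchors <- function(custom_means, custom_fits) {
  if (is.numeric(custom_means)) {
    custom_means <- tibble::tibble(period = names(custom_means) %||%
                                     as.character(seq_along(custom_means)),
                                   mean = unname(custom_means))
  }
  if (any(!is.finite(custom_means$mean))) {
    bad <- custom_means$period[!is.finite(custom_means$mean)]
    abort(paste0("Missing group mean for period(s): ",
                 paste(bad, collapse = ", ")),
          class = "thermoskin_validation_error")
  }
  if (is.data.frame(custom_fits)) custom_fits <- custom_fits$fit
  preds <- purrr::map(custom_fits, function(f) predict_reference(f,
                                                 custom_means$mean))
  tibble::tibble(period = custom_means$period,
                 y_prime = purrr::reduce(preds, `+`) / length(preds))
}

#' Sensor-type temperature estimates at the anchor temperatures
#'
#' Inverse-predicts, for every individual sensor fit, the sensor temperature
#' at each anchor reference temperature.
#'
#' @param fits Output of [sensor_reference_fits()].
#' @param anchors Output of [compute_anchors()].
#' @param type_map Named character vector mapping coverage conditions to the
#'   sensor types being compared.
#'
#' @return A tibble: `sensor_type`, `velocity`, `replicate`, `period`,
#'   `x_prime`.
#' @export
sensor_type_estimates <- function(fits, anchors,
                                  type_map = c(custom_tape = "custom",
                                               grant_tape = "grant",
                                               ibutton_tape = "ibutton")) {
  fits |>
    dplyr::filter(.data$coverage %in% names(type_map)) |>
    dplyr::mutate(sensor_type = unname(type_map[.data$coverage])) |>
    dplyr::rowwise() |>
    dplyr::reframe(sensor_type = .data$sensor_type,
                   velocity = .data$velocity,
                   replicate = .data$replicate,
                   period = anchors$period,
                   x_prime = inverse_predict(.data$fit, anchors$y_prime))
}

INTERSENSOR_PAIRS <- list(c("grant", "custom"),
                          c("ibutton", "custom"),
                          c("ibutton", "grant"))

#' Paired inter-sensor differences at common reference temperatures
#'
#' Within each period (and velocity, if present), forms the per-replicate
#' differences between sensor types (Grant - custom, iButton - custom,
#' iButton - Grant) and summarizes them as a group mean with an unadjusted
#' 95% t-interval.  Negative means indicate the first-listed sensor reading
#' cooler.
#'
#' @param estimates A tibble with columns `sensor_type`, `replicate`,
#'   `period`, `x_prime` and optionally `velocity` (as from
#'   [sensor_type_estimates()]).
#' @param level Confidence level.
#'
#' @return A tibble: `pair`, `period` (and `velocity`), `mean`, `ci_low`,
#'   `ci_high`, `n`.
#' @export
intersensor_differences <- function(estimates, level = 0.95) {
  group_cols <- intersect(c("velocity", "period"), names(estimates))
  purrr::map_dfr(INTERSENSOR_PAIRS, function(pr) {
    a <- dplyr::filter(estimates, .data$sensor_type == pr[1])
    b <- dplyr::filter(estimates, .data$sensor_type == pr[2])
    joined <- dplyr::inner_join(a, b,
                                by = c(group_cols, "replicate"),
                                suffix = c("_a", "_b"))
    n_a <- nrow(a); n_b <- nrow(b)
    if (n_a != n_b || nrow(joined) != n_a) {
      abort(sprintf("Unbalanced replicate counts for pair %s-%s.",
                    pr[1], pr[2]),
            class = "thermoskin_unbalanced_error")
    }
    joined |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::reframe(summarize_mean_ci(.data$x_prime_a - .data$x_prime_b,
                                       level = level)) |>
      dplyr::mutate(pair = paste0(pr[1], "-", pr[2]), .before = 1)
  })
}
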