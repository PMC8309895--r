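#' Pair disturbed steady states with the matching undisturbed reference
#'
#' For every sensor-bearing or tape-covered steady state, finds the
#' undisturbed reference temperature from the bare-surface runs of the same
#' air velocity.  When a bare run exists for the same replicate, pairing is by
#' identity of (velocity, replicate, step); otherwise the undisturbed surface
#' temperature is interpolated linearly against the plate setpoint across the
#' bare runs of that velocity.
#'
#' @param states Steady-state table from [rig_steady_states()] containing both
#'   covered and `bare` rows.
#'
#' @return A tibble of paired steady states: run identifiers, `t_sen`, `t_d`
#'   (corrected disturbed surface), `t_u` (corrected undisturbed surface from
#'   the matched bare run), `ambient`, and `gradient = t_u - ambient`, plus
#'   the signed error measures `disturbance`, `bias_from_td`, `bias_from_tu`.
#' @export
match_undisturbed <- function(states) {
  bare <- dplyr::filter(states, .data$coverage == "bare")
  dist <- dplyr::filter(states, .data$coverage != "bare")
  missing_v <- setdiff(unique(dist$velocity), unique(bare$velocity))
  if (length(missing_v)) {
    offending <- dist |>
      dplyr::filter(.data$velocity %in% missing_v) |>
      dplyr::pull("run_id") |>
      unique()
    abort(paste0("No bare-surface run for velocity ",
                 paste(missing_v, collapse = ", "), "; unmatched runs: ",
                 paste(offending, collapse = ", ")),
          class = "thermoskin_unmatched_error")
  }
  bare_key <- bare |>
    dplyr::select("velocity", "replicate", "step", t_u = "t_u_own")
  paired <- dist |>
    dplyr::left_join(bare_key, by = c("velocity", "replicate", "step"))
  # fall back to interpolation vs plate setpoint where no replicate-level
  # bare run exists
  need <- is.na(paired$t_u)
  if (any(need)) {
    interp <- split(bare, bare$velocity)
    paired$t_u[need] <- purrr::map2_dbl(
      paired$velocity[need], paired$setpoint[need],
      function(v, sp) {
        b <- interp[[as.character(v)]]
        approx(b$setpoint, b$t_u_own, xout = sp, ties = mean, rule = 2)$y
      })
  }
  paired |>
    dplyr::select("run_id", "coverage", "velocity", "replicate", "step",
                  "setpoint", "ambient", "t_sen", "t_d", "t_u", "corr_d",
                  "qualified") |>
    dplyr::mutate(gradient = .data$t_u - .data$ambient,
                  disturbance = compute_disturbance(.data$t_d, .data$t_u),
                  bias_from_td = compute_bias(.data$t_sen, .data$t_d),
                  bias_from_tu = compute_bias(.data$t_sen, .data$t_u))
}

#' Local temperature disturbance
#'
#' The signed change of the local surface temperature caused by the presence
#' of the sensor/attachment: `disturbance = t_d - t_u`.  Positive means the
#' coverage warms the underlying surface.
#'
#' @param t_d Corrected disturbed surface temperature, degC.
#' @param t_u Corrected undisturbed surface temperature, degC.
#' @return Disturbance, degC.
#' @export
#' @examples
#' compute_disturbance(33.3, 34.2)  # un-taped iButton at 0.5 m/s: -0.9
compute_disturbance <- function(t_d, t_u) t_d - t_u

#' Sensor measurement bias
#'
#' `bias = t_sen - t_ref`, where the reference is either the disturbed
#' surface temperature directly beneath the sensor (bias from T_d) or the
#' corresponding undisturbed surface (bias from T_u).  The two forms satisfy
#' `bias_from_tu = bias_from_td + disturbance` exactly.
#'
#' @param t_sen Surface sensor reading, degC.
#' @param t_ref Reference temperature (`t_d` or matched `t_u`), degC.
#' @return Signed bias, degC.
#' @export
#' @examples
#' compute_bias(31.0, 33.3)  # -2.3
compute_bias <- function(t_sen, t_ref) t_sen - t_ref

#' Mean with unadjusted t-based confidence interval
#'
#' `mean +/- qt(1 - alpha/2, n - 1) * sd / sqrt(n)`; intervals are unadjusted
#' for multiplicity.
#'
#' @param values Numeric values (n >= 2).
#' @param level Confidence level.
#'
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' summarize_mean_ci(1:5)  # mean 3, CI (1.037, 4.963)
summarize_mean_ci <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) {
    abort("At least 2 values are required for a confidence interval.",
          class = "thermoskin_undefined_ci")
  }
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  tibble::tibble(mean = m, ci_low = m - half, ci_high = m + half, n = n)
}

#' Straight-line fit of an error measure against the surface gradient
#'
#' Ordinary least squares of disturbance or bias values on the
#' surface-to-environment gradient (`t_u - ambient`), used to display and
#' check the linear growth of errors with the gradient.
#'
#' @param values Error values, degC (>= 3).
#' @param gradients Matching gradients, degC.
#'
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_vs_gradient <- function(values, gradients) {
  keep <- is.finite(values) & is.finite(gradients)
  values <- values[keep]; gradients <- gradients[keep]
  if (length(values) < 3) {
    abort("At least 3 points are required to fit against the gradient.",
          class = "thermoskin_insufficient_data")
  }
  fit <- lm(values ~ gradients)
  tibble::tibble(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 n = length(values))
}

#' Gradient fits for every coverage, velocity and error form
#'
#' @param paired Paired steady states from [match_undisturbed()].
#' @return A tibble with one fit per coverage x velocity x form.
#' @export
gradient_fits <- function(paired) {
  paired |>
    tidyr::pivot_longer(c("disturbance", "bias_from_td", "bias_from_tu"),
                        names_to = "form", values_to = "value") |>
    dplyr::filter(!(.data$form != "disturbance" & is.na(.data$t_sen))) |>
    dplyr::group_by(.data$coverage, .data$velocity, .data$form) |>
    dplyr::reframe(fit_vs_gradient(.data$value, .data$gradient))
}

#' Error estimate at a fixed sensor temperature
#'
#' Summarizes disturbance or bias at a realistic sensor reading (31 degC by
#' default): within each replicate the chosen error form is regressed
#' linearly on the sensor temperature across the five steps and evaluated at
#' `t_fixed`; the replicate values are then summarized as a mean with an
#' unadjusted 95% t-interval (df = n - 1).
#'
#' @param paired Paired steady states from [match_undisturbed()] (one
#'   coverage x velocity group or several; groups are handled separately).
#' @param form `"bias_from_td"`, `"bias_from_tu"` or `"disturbance"`.
#' @param t_fixed Sensor temperature at which to evaluate, degC.
#' @param level Confidence level.
#'
#' @return A tibble with one row per coverage x velocity: `form`,
#'   `evaluated_at`, `mean`, `ci_low`, `ci_high` (NA with a warning when only
#'   one replicate is available), `n`.
#' @export
evaluate_at_fixed_sensor_temp <- function(paired,
                                          form = c("bias_from_td",
                                                   "bias_from_tu",
                                                   "disturbance"),
                                          t_fixed = 31, level = 0.95) {
  form <- match.arg(form)
  paired |>
    dplyr::group_by(.data$coverage, .data$velocity) |>
    dplyr::group_map(function(df, key) {
      per_rep <- df |>
        dplyr::group_by(.data$replicate) |>
        dplyr::group_map(function(rep_df, rep_key) {
          ok <- is.finite(rep_df$t_sen) & is.finite(rep_df[[form]])
          if (sum(ok) < 2 || sd(rep_df$t_sen[ok]) == 0) {
            warn(sprintf("Replicate %s excluded: fewer than 2 usable steady states.",
                         rep_key$replicate),
                 class = "thermoskin_replicate_excluded")
            return(NULL)
          }
          fit <- lm(rep_df[[form]][ok] ~ rep_df$t_sen[ok])
          tibble::tibble(replicate = rep_key$replicate,
                         value = unname(coef(fit)[1] + coef(fit)[2] * t_fixed))
        }) |>
        dplyr::bind_rows()
      n <- nrow(per_rep)
      if (n == 0) return(NULL)
      if (n >= 2) {
        s <- summarize_mean_ci(per_rep$value, level = level)
      } else {
        warn("Single replicate: point estimate only, CI undefined.",
             class = "thermoskin_undefined_ci_warning")
        s <- tibble::tibble(mean = per_rep$value, ci_low = NA_real_,
                            ci_high = NA_real_, n = 1L)
      }
      dplyr::bind_cols(key, tibble::tibble(form = form,
                                           evaluated_at = t_fixed), s)
    }) |>
    dplyr::bind_rows()
}

#' Fixed-temperature bias summary for every coverage condition
#'
#' Both bias forms evaluated at a fixed sensor temperature for every
#' sensor-bearing coverage x velocity, in the layout of a bias summary table.
#'
#' @inheritParams evaluate_at_fixed_sensor_temp
#' @return A tibble of [evaluate_at_fixed_sensor_temp()] results for
#'   `bias_from_td` and `bias_from_tu`.
#' @export
table1_summary <- function(paired, t_fixed = 31, level = 0.95) {
  sensor_states <- dplyr::filter(paired, !is.na(.data$t_sen))
  purrr::map_dfr(c("bias_from_td", "bias_from_tu"), function(f) {
    evaluate_at_fixed_sensor_temp(sensor_states, form = f,
                                  t_fixed = t_fixed, level = level)
  })
}
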