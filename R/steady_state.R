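#' Extract per-step steady-state means from a rig run
#'
#' Means and SDs of every temperature channel over minutes 21-29 (half-open,
#' `[21, 29)`) of each 30-min plate step.  A step is `qualified` when every
#' analyzed channel has a within-window SD below `sd_tol` (0.05 degC); a step
#' whose analysis window is incomplete is marked unqualified with a reason.
#'
#' @param run A `rig_run` tibble from [simulate_rig_run()] or
#'   [load_run_csv()].
#' @param sd_tol Steady-state SD gate, degC.
#' @param window_min Analysis window within each step, minutes from step
#'   start (half-open).
#'
#' @return A tibble with one row per step x channel: `step`, `channel`,
#'   `mean`, `sd`, `n`, `qualified`, `reason`.
#' @export
extract_step_means <- function(run, sd_tol = 0.05, window_min = c(21, 29)) {
  meta <- attr(run, "meta")
  if (is.null(meta)) {
    abort("`run` carries no metadata; expected a `rig_run`.",
          class = "thermoskin_validation_error")
  }
  dur <- meta$step_duration
  si <- meta$sample_interval
  n_expected <- as.integer(diff(window_min) * 60 / si)
  channels <- setdiff(names(run), "time_s")

  long <- run |>
    tidyr::pivot_longer(dplyr::all_of(channels), names_to = "channel",
                        values_to = "value") |>
    dplyr::mutate(step = floor(.data$time_s / dur) + 1,
                  rel_s = .data$time_s - (.data$step - 1) * dur) |>
    dplyr::filter(.data$step <= 5,
                  .data$rel_s >= window_min[1] * 60,
                  .data$rel_s < window_min[2] * 60)

  out <- long |>
    dplyr::group_by(.data$step, .data$channel) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  # restore any step with no samples in the window at all
  out <- tidyr::complete(out, step = 1:5, channel = channels,
                         fill = list(n = 0L))
  out |>
    dplyr::group_by(.data$step) |>
    dplyr::mutate(
      complete_win = all(.data$n == n_expected),
      qualified = .data$complete_win & all(.data$sd < sd_tol),
      reason = dplyr::case_when(
        !.data$complete_win ~ "truncated step",
        !.data$qualified ~ "channel SD >= tolerance",
        TRUE ~ NA_character_)) |>
    dplyr::ungroup() |>
    dplyr::select(-"complete_win") |>
    dplyr::arrange(.data$step, .data$channel)
}

#' Correct a subsurface reading to the surface via Fourier's law
#'
#' Assuming a linear in-slab temperature profile, the readings of two embedded
#' sensors at depths `z1 < z2` are extrapolated to the surface (z = 0):
#' `surface = T_z1 + (T_z1 - T_z2) * z1 / (z2 - z1)`.  In the simulated
#' columns the in-slab profile is exactly linear, so this recovers the true
#' surface temperature.  It is applied to reference channels only, never to
#' the surface sensor reading itself.
#'
#' @param t_z1,t_z2 Temperatures at depths `z1` and `z2`, degC (vectorized).
#' @param z1,z2 Depths below the surface, m, with `0 < z1 < z2`.
#'
#' @return A tibble with `surface_temp` (degC) and `correction_magnitude`
#'   (`|surface_temp - t_z1|`, degC).
#' @export
#' @examples
#' correct_to_surface(33.0, 31.0, 1e-3, 5e-3)  # surface 33.5 degC
correct_to_surface <- function(t_z1, t_z2, z1, z2) {
  if (!(z1 > 0) || z2 <= z1) {
    abort("Invalid geometry: depths must satisfy 0 < z1 < z2.",
          class = "thermoskin_geometry_error")
  }
  surface <- t_z1 + (t_z1 - t_z2) * z1 / (z2 - z1)
  tibble::tibble(surface_temp = surface,
                 correction_magnitude = abs(surface - t_z1))
}

#' Steady-state table for a set of rig runs
#'
#' Runs [extract_step_means()] on every run, spreads the channels, and applies
#' the two-depth surface correction to both reference columns.  The surface
#' sensor channel `t_sen` is left uncorrected, consistent with normal sensor
#' use.
#'
#' @param design A `rig_design` from [simulate_rig_design()], or a list with
#'   `manifest` and `runs` in the same layout.
#' @param sd_tol Steady-state SD gate passed to [extract_step_means()].
#'
#' @return A tibble with one row per run x step: run identifiers, `setpoint`,
#'   `ambient`, `t_sen` (NA for sensorless coverages), corrected surface
#'   temperatures `t_d` (disturbed column) and `t_u_own` (undisturbed column
#'   of the same run), correction magnitudes `corr_d`, `corr_u`, and
#'   `qualified`.
#' @export
rig_steady_states <- function(design, sd_tol = 0.05) {
  purrr::map2_dfr(design$runs, names(design$runs), function(run, id) {
    meta <- attr(run, "meta")
    sm <- extract_step_means(run, sd_tol = sd_tol)
    wide <- sm |>
      dplyr::select("step", "channel", "mean") |>
      tidyr::pivot_wider(names_from = "channel", values_from = "mean")
    if (!"t_sen" %in% names(wide)) wide$t_sen <- NA_real_
    qual <- sm |>
      dplyr::group_by(.data$step) |>
      dplyr::summarise(qualified = all(.data$qualified), .groups = "drop")
    d <- correct_to_surface(wide$t_z1_dist, wide$t_z2_dist, meta$z1, meta$z2)
    u <- correct_to_surface(wide$t_z1_undist, wide$t_z2_undist,
                            meta$z1, meta$z2)
    tibble::tibble(run_id = id,
                   coverage = meta$coverage,
                   velocity = meta$velocity,
                   replicate = meta$replicate,
                   step = wide$step,
                   setpoint = meta$plate_setpoints[wide$step],
                   ambient = wide$ambient,
                   t_sen = wide$t_sen,
                   t_d = d$surface_temp,
                   corr_d = d$correction_magnitude,
                   t_u_own = u$surface_temp,
                   corr_u = u$correction_magnitude,
                   qualified = qual$qualified[match(wide$step, qual$step)])
  })
}
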