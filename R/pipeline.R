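#' Run the full rig analysis end to end
#'
#' Simulates the experimental design (6 coverages x `replicates` x 2 air
#' velocities by default), extracts per-step steady states, corrects the
#' reference channels to the surface, pairs disturbed states with the bare
#' runs, and produces the disturbance/bias tables, gradient fits, the
#' fixed-temperature bias summary, and the per-sensor reference fits.
#' Deterministic for a fixed `master_seed`.
#'
#' @inheritParams simulate_rig_design
#' @param t_fixed Sensor temperature for the bias summary, degC.
#'
#' @return A list of class `rig_results`: `manifest`, `steady_states`,
#'   `paired`, `gradient_fits`, `table1`, `sensor_fits`, `params`.
#' @export
#' @examples
#' \donttest{
#' res <- run_rig_suite(replicates = 2, master_seed = 1)
#' res$table1
#' }
run_rig_suite <- function(material = material_props(),
                          coverages = default_coverages(),
                          velocities = c(0.2, 0.5),
                          replicates = 5,
                          sensors = default_sensors(),
                          master_seed = 1L,
                          t_fixed = 31) {
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", label, "] ", conditionMessage(e)), parent = e)
    })
  }
  design <- stage("simulate", simulate_rig_design(
    material = material, coverages = coverages, velocities = velocities,
    replicates = replicates, sensors = sensors, master_seed = master_seed))
  states <- stage("steady-states", rig_steady_states(design))
  paired <- stage("match", match_undisturbed(states))
  gfits <- stage("gradient-fits", gradient_fits(paired))
  tbl1 <- if (replicates >= 2) {
    stage("fixed-point", table1_summary(paired, t_fixed = t_fixed))
  } else {
    stage("fixed-point", suppressWarnings(
      table1_summary(paired, t_fixed = t_fixed)))
  }
  sfits <- stage("reference-fits", sensor_reference_fits(paired))
  structure(list(manifest = design$manifest,
                 steady_states = states,
                 paired = paired,
                 gradient_fits = gfits,
                 table1 = tbl1,
                 sensor_fits = sfits,
                 params = list(master_seed = master_seed, t_fixed = t_fixed,
                               replicates = replicates,
                               velocities = velocities,
                               fixed_point_method = paste(
                                 "per-replicate OLS of bias vs sensor",
                                 "temperature evaluated at t_fixed"))),
            class = "rig_results")
}

#' @export
print.rig_results <- function(x, ...) {
  cat(sprintf("<rig_results>  %d runs, %d paired steady states\n",
              nrow(x$manifest), nrow(x$paired)))
  cat("Fixed-temperature bias summary ($table1):\n")
  print(x$table1)
  invisible(x)
}

#' Analyze a human-trial dataset
#'
#' Computes weighted-mean skin temperature per participant and sensor type,
#' detects each participant's sweat onset from the skin vapor pressure,
#' builds the seven summary periods (FL1-PS from the detected onset), takes
#' period means, and summarizes the within-participant inter-sensor
#' differences.
#'
#' @param trial A `trial_dataset` from [simulate_human_trial()] (or any list
#'   with `tsk`, `humidity`, `exercise_start_min` in that layout).
#'
#' @return A list of class `trial_results`: `weighted` (weighted-mean series),
#'   `onsets` (detected onsets), `period_values` (participant x type x period
#'   means), `custom_group_means` (anchor inputs for the model comparison),
#'   `differences`.
#' @export
analyze_human_trial <- function(trial) {
  weighted <- trial$tsk |>
    tidyr::pivot_wider(names_from = "site", values_from = "temp") |>
    dplyr::mutate(value = weighted_mean_tsk(.data$chest, .data$arm,
                                            .data$thigh, .data$leg)) |>
    dplyr::select("participant", "sensor_type", "time_min", "value")

  onsets <- trial$humidity |>
    dplyr::mutate(vp = vapor_pressure(.data$temp, .data$rh)) |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_map(function(df, key) {
      dplyr::bind_cols(key, detect_sweat_onset(df, trial$exercise_start_min))
    }) |>
    dplyr::bind_rows()

  period_values <- weighted |>
    dplyr::group_by(.data$participant, .data$sensor_type) |>
    dplyr::group_map(function(df, key) {
      on <- onsets$time_min[onsets$participant == key$participant]
      periods <- trial_periods(if (length(on)) on[1] else NA)
      dplyr::bind_cols(key,
                       dplyr::rename(period_means(df, periods),
                                     value = "mean"))
    }) |>
    dplyr::bind_rows()

  custom_group_means <- period_values |>
    dplyr::filter(.data$sensor_type == "custom") |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")

  structure(list(weighted = weighted,
                 onsets = onsets,
                 period_values = period_values,
                 custom_group_means = custom_group_means,
                 differences = trial_intersensor_differences(
                   dplyr::select(period_values, "participant", "sensor_type",
                                 "period", "value"))),
            class = "trial_results")
}

#' Compare model-derived inter-sensor differences with a human trial
#'
#' Implements the inverse-prediction matching procedure: for each air
#' velocity, the custom-sensor reference fits convert the seven
#' custom-thermistor group means from the trial into model reference
#' anchors; every individual sensor's temperature at each anchor is then
#' obtained by inverse prediction, and paired inter-sensor differences are
#' summarized per period.  Human-trial differences are appended for
#' side-by-side display.
#'
#' @param rig A `rig_results` from [run_rig_suite()].
#' @param trial_results A `trial_results` from [analyze_human_trial()], or a
#'   tibble of custom group means (`period`, `mean`).
#'
#' @return A tibble: `pair`, `period`, `source` (`model-0.2`, `model-0.5`,
#'   `human`), `mean`, `ci_low`, `ci_high`, `n`.
#' @export
compare_with_trial <- function(rig, trial_results) {
  if (inherits(trial_results, "trial_results")) {
    custom_means <- trial_results$custom_group_means
    human <- trial_results$differences |>
      dplyr::mutate(source = "human")
  } else {
    custom_means <- trial_results
    human <- NULL
  }
  model <- purrr::map_dfr(unique(rig$sensor_fits$velocity), function(v) {
    fits_v <- dplyr::filter(rig$sensor_fits, .data$velocity == v)
    anchors <- compute_anchors(
      custom_means,
      dplyr::filter(fits_v, .data$coverage == "custom_tape")$fit)
    est <- sensor_type_estimates(fits_v, anchors)
    intersensor_differences(est) |>
      dplyr::mutate(source = sprintf("model-%.1f", v)) |>
      dplyr::select(-"velocity")
  })
  dplyr::bind_rows(model, human) |>
    dplyr::select("pair", "period", "source", "mean", "ci_low", "ci_high",
                  "n")
}
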