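# first-order network time constant of the slab (dominant conduction mode)
network_time_constant <- function(material) {
  material$thickness^2 / (pi^2 * material$diffusivity)
}

quantize <- function(x, resolution) {
  if (resolution > 0) round(x / resolution) * resolution else x
}

observe_channel <- function(truth, spec) {
  obs <- truth * spec$true_gain + spec$true_offset +
    rnorm(length(truth), 0, spec$noise_sd)
  quantize(obs, spec$resolution)
}

# piecewise single-pole relaxation through the five steps; `targets` is the
# per-step steady value of one channel, continuity is kept across steps
relax_steps <- function(targets, tau, step_duration, sample_interval) {
  n_per <- step_duration / sample_interval
  rel <- seq_len(n_per) * sample_interval  # time elapsed within step
  out <- numeric(0)
  prev <- targets[1]  # model pre-equilibrated at the first setpoint
  for (tg in targets) {
    v <- tg + (prev - tg) * exp(-rel / tau)
    out <- c(out, v)
    prev <- v[n_per]
  }
  out
}

#' Simulate one rig experimental run
#'
#' Generates the multichannel temperature log of a single coverage x velocity
#' x replicate run: five plate-temperature steps, each node relaxing
#' first-order toward the steady state given by [solve_thermal_network()] with
#' a time constant derived from the slab diffusivity and thickness (plus the
#' sensor's own response time), observed every `sample_interval` seconds with
#' per-sensor gain/offset, Gaussian noise and quantization.
#'
#' @param material A [material_props()] row.
#' @param coverage A [coverage_spec()] row.
#' @param config A [rig_config()].
#' @param sensors Sensor specification table, as [default_sensors()].
#' @param replicate Replicate id recorded in the metadata.
#' @param seed Integer seed; identical seeds give identical runs.
#'
#' @return A tibble of class `rig_run` with columns `time_s`, `ambient`,
#'   `t_z1_dist`, `t_z2_dist`, `t_z1_undist`, `t_z2_undist` and, for
#'   sensor-bearing coverages, `t_sen`.  Run metadata (coverage, velocity,
#'   replicate, seed, physical parameters, a steady-state warning flag) is
#'   stored in `attr(, "meta")`.
#' @export
#' @examples
#' run <- simulate_rig_run(material_props(), default_coverages()[1, ],
#'                         rig_config(air_velocity = 0.5), seed = 1)
#' dplyr::glimpse(run)
simulate_rig_run <- function(material, coverage, config,
                             sensors = default_sensors(),
                             replicate = 1L, seed = 1L) {
  stopifnot(inherits(config, "rig_config"))
  nodes <- solve_thermal_network(material, coverage, config,
                                 config$plate_setpoints)
  tau <- network_time_constant(material)
  dur <- config$step_duration
  si <- config$sample_interval
  warn_flag <- tau >= dur / 3
  if (warn_flag) {
    warn("Network time constant >= step_duration / 3: steady state may not be reached.",
         class = "thermoskin_steady_state_warning")
  }

  n <- 5 * dur / si
  time_s <- seq_len(n) * si - si  # 0, si, ..., end
  spec_of <- function(type) sensors[sensors$sensor_type == type, ][1, ]
  emb <- spec_of("embedded")
  tau_emb <- tau + emb$response_time

  set.seed(seed)
  out <- tibble::tibble(time_s = time_s)
  out$ambient <- observe_channel(rep(config$ambient_temp, n), emb)
  for (ch in c("t_z1_disturbed", "t_z2_disturbed",
               "t_z1_undisturbed", "t_z2_undisturbed")) {
    truth <- relax_steps(nodes[[ch]], tau_emb, dur, si)
    short <- sub("disturbed$", "dist", sub("undisturbed$", "undist", ch))
    out[[short]] <- observe_channel(truth, emb)
  }
  sensor_type <- coverage$sensor_type
  if (!is.na(sensor_type)) {
    sspec <- spec_of(sensor_type)
    truth <- relax_steps(nodes$sensor_node, tau + sspec$response_time, dur, si)
    out$t_sen <- observe_channel(truth, sspec)
  }

  meta <- list(coverage = coverage$name,
               sensor_type = sensor_type,
               velocity = config$air_velocity,
               replicate = replicate,
               seed = seed,
               plate_setpoints = config$plate_setpoints,
               step_duration = dur,
               sample_interval = si,
               ambient_temp = config$ambient_temp,
               z1 = config$z1, z2 = config$z2,
               material = as.list(tibble::as_tibble(material)),
               coverage_params = as.list(tibble::as_tibble(coverage)),
               tau_network = tau,
               steady_warning = warn_flag)
  attr(out, "meta") <- meta
  class(out) <- c("rig_run", class(out))
  out
}

#' Simulate the full rig experimental design
#'
#' Enumerates coverages x replicates x velocities (6 x 5 x 2 = 60 runs by
#' default) and simulates each run with a per-run seed derived
#' deterministically from `master_seed`.
#'
#' @param material A [material_props()] row.
#' @param coverages Coverage table, as [default_coverages()].
#' @param velocities Air velocities to run, m/s.
#' @param replicates Number of replicates per condition.
#' @param sensors Sensor specification table.
#' @param config_fn Function `(velocity, seed)` returning the [rig_config()]
#'   for one run; defaults to `rig_config(air_velocity = velocity, seed = seed)`.
#' @param master_seed Master seed controlling all randomness.
#'
#' @return A list of class `rig_design` with elements `manifest` (tibble:
#'   `run_id`, `coverage`, `velocity`, `replicate`, `seed`) and `runs`
#'   (named list of `rig_run` tibbles).
#' @export
simulate_rig_design <- function(material = material_props(),
                                coverages = default_coverages(),
                                velocities = c(0.2, 0.5),
                                replicates = 5,
                                sensors = default_sensors(),
                                config_fn = NULL,
                                master_seed = 1L) {
  config_fn <- config_fn %||%
    function(velocity, seed) rig_config(air_velocity = velocity, seed = seed)
  manifest <- tidyr::expand_grid(velocity = velocities,
                                 replicate = seq_len(replicates),
                                 coverage = coverages$name)
  set.seed(master_seed)
  manifest$seed <- sample.int(.Machine$integer.max - 1L, nrow(manifest))
  manifest$run_id <- sprintf("%s_v%02.0f_r%d", manifest$coverage,
                             100 * manifest$velocity, manifest$replicate)
  manifest <- dplyr::select(manifest, "run_id", "coverage", "velocity",
                            "replicate", "seed")
  runs <- purrr::pmap(manifest, function(run_id, coverage, velocity,
                                         replicate, seed) {
    cov <- coverages[coverages$name == coverage, ]
    class(cov) <- unique(c("coverage_spec", class(cov)))
    simulate_rig_run(material, cov, config_fn(velocity, seed),
                     sensors = sensors, replicate = replicate, seed = seed)
  })
  names(runs) <- manifest$run_id
  structure(list(manifest = manifest, runs = runs), class = "rig_design")
}

#' Simulate a calibration-chamber run
#'
#' A precision reference (recorded every 5 s) and the sensors under test
#' (recorded every 10 s) track the chamber temperature through stepped
#' plateaus covering 15-40 degC.  The chamber approaches each setpoint
#' first-order; sensors read the chamber truth through their linear
#' instrument error, noise and quantization.
#'
#' @param setpoints Chamber setpoints, degC.
#' @param sensors A tibble with a `sensor_id` column plus [sensor_spec()]
#'   columns, one row per sensor under test.
#' @param step_duration Plateau duration, s (>= 80 min in the standard
#'   procedure).
#' @param chamber_tau Chamber first-order time constant, s.
#' @param ref_noise_sd,ref_resolution Reference read noise (degC) and
#'   quantization step.
#' @param seed Integer seed.
#'
#' @return A list of class `calibration_run`: `reference` (tibble `time_s`,
#'   `value`), `sensors` (tibble `time_s`, `sensor_id`, `value`), and `truth`
#'   (tibble `time_s`, `value`, the noiseless chamber temperature at the
#'   reference sampling grid).
#' @export
simulate_calibration_run <- function(setpoints = seq(15, 40, by = 5),
                                     sensors = tibble::tibble(
                                       sensor_id = "custom_1",
                                       sensor_spec("custom")),
                                     step_duration = 80 * 60,
                                     chamber_tau = 300,
                                     ref_noise_sd = 0.002,
                                     ref_resolution = 0.01,
                                     seed = 1L) {
  set.seed(seed)
  ref_si <- 5
  sen_si <- 10
  n_ref <- length(setpoints) * step_duration / ref_si
  t_ref <- seq_len(n_ref) * ref_si - ref_si
  truth_ref <- relax_steps(setpoints, chamber_tau, step_duration, ref_si)
  reference <- tibble::tibble(
    time_s = t_ref,
    value = quantize(truth_ref + rnorm(n_ref, 0, ref_noise_sd),
                     ref_resolution))

  keep <- t_ref %% sen_si == 0
  t_sen <- t_ref[keep]
  truth_sen <- truth_ref[keep]
  sensor_obs <- purrr::map(seq_len(nrow(sensors)), function(i) {
    sp <- sensors[i, ]
    tibble::tibble(time_s = t_sen, sensor_id = sp$sensor_id,
                   value = observe_channel(truth_sen, sp))
  })
  structure(list(reference = reference,
                 sensors = dplyr::bind_rows(sensor_obs),
                 truth = tibble::tibble(time_s = t_ref, value = truth_ref),
                 setpoints = setpoints),
            class = "calibration_run")
}
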