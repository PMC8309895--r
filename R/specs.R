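#' Thermal properties of the skin simulant
#'
#' Describes the silicone slab used as the skin simulant. Defaults correspond
#' to a polydimethylsiloxane elastomer with skin-like thermal properties:
#' conductivity ~0.23 W/(m K), diffusivity ~12.8e-8 m^2/s, emissivity ~0.9,
#' density ~1350 kg/m^3, and a 10 mm slab.
#'
#' @param conductivity Thermal conductivity, W/(m K).
#' @param diffusivity Thermal diffusivity, m^2/s.
#' @param emissivity Surface emissivity, dimensionless, in (0, 1].
#' @param density Density, kg/m^3.
#' @param thickness Slab thickness, m.
#'
#' @return A one-row tibble of class `material_props`.
#' @export
#' @examples
#' material_props()
material_props <- function(conductivity = 0.23,
                           diffusivity = 12.8e-8,
                           emissivity = 0.90,
                           density = 1350,
                           thickness = 0.010) {
  vals <- c(conductivity = conductivity, diffusivity = diffusivity,
            emissivity = emissivity, density = density, thickness = thickness)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All material properties must be finite and > 0.",
          class = "thermoskin_validation_error")
  }
  if (emissivity > 1) {
    abort("`emissivity` must lie in (0, 1].",
          class = "thermoskin_validation_error")
  }
  out <- tibble::tibble(conductivity = conductivity, diffusivity = diffusivity,
                        emissivity = emissivity, density = density,
                        thickness = thickness)
  class(out) <- c("material_props", class(out))
  out
}

COVERAGE_NAMES <- c("custom_tape", "grant_tape", "ibutton_tape",
                    "ibutton_only", "tape_only", "bare")

# sensor type sitting at the sensor node of each coverage condition (NA = none)
COVERAGE_SENSOR <- c(custom_tape = "custom", grant_tape = "grant",
                     ibutton_tape = "ibutton", ibutton_only = "ibutton",
                     tape_only = NA_character_, bare = NA_character_)

#' Surface-coverage condition
#'
#' A surface-coverage condition describes what sits on the skin simulant above
#' the reference thermistor: a sensor and/or attachment tape, or nothing
#' (`bare`). Thermally, a coverage is a contact resistance between surface and
#' sensor node, a top resistance between sensor node and the boundary layer,
#' and an area factor that scales the boundary conductance for fin-like
#' conductive sensor bodies (which shed extra heat to the air).
#'
#' @param name One of `"custom_tape"`, `"grant_tape"`, `"ibutton_tape"`,
#'   `"ibutton_only"`, `"tape_only"`, `"bare"`.
#' @param contact_resistance Surface-to-sensor contact resistance, m^2 K/W.
#' @param top_resistance Sensor-to-boundary resistance, m^2 K/W.
#' @param area_factor Convective enhancement factor (>= 1); 1 means no fin
#'   effect.
#' @param footprint_area Covered footprint, m^2 (metadata; the network is
#'   per-unit-area).
#'
#' @return A one-row tibble of class `coverage_spec`.
#' @seealso [default_coverages()]
#' @export
coverage_spec <- function(name,
                          contact_resistance = 0,
                          top_resistance = 0,
                          area_factor = 1,
                          footprint_area = 1.25e-3) {
  name <- match.arg(name, COVERAGE_NAMES)
  if (!is.finite(contact_resistance) || contact_resistance < 0 ||
      !is.finite(top_resistance) || top_resistance < 0) {
    abort("Coverage resistances must be finite and >= 0.",
          class = "thermoskin_validation_error")
  }
  if (!is.finite(area_factor) || area_factor < 1) {
    abort("`area_factor` must be >= 1.", class = "thermoskin_validation_error")
  }
  if (name == "bare" &&
      (contact_resistance != 0 || top_resistance != 0 || area_factor != 1)) {
    abort("`bare` coverage must have zero added resistances and area_factor 1.",
          class = "thermoskin_validation_error")
  }
  out <- tibble::tibble(name = name,
                        contact_resistance = contact_resistance,
                        top_resistance = top_resistance,
                        area_factor = area_factor,
                        footprint_area = footprint_area,
                        sensor_type = unname(COVERAGE_SENSOR[name]))
  class(out) <- c("coverage_spec", class(out))
  out
}

#' Default surface-coverage conditions
#'
#' The six coverage conditions of the rig design with thermal parameters chosen
#' so that the simulated disturbance signs reproduce the observed pattern:
#' tape-only and custom-thermistor-plus-tape warm the underlying surface;
#' iButton-only and Grant-plus-tape cool it (fin effect of the metallic body);
#' iButton-plus-tape warms at 0.5 m/s but cools at 0.2 m/s.
#'
#' @return A six-row tibble, one [coverage_spec()] per row.
#' @export
#' @examples
#' default_coverages()
default_coverages <- function() {
  dplyr::bind_rows(
    coverage_spec("custom_tape",  0.0045, 0.0025, 1.0),
    coverage_spec("grant_tape",   0.0070, 0.0120, 2.0),
    coverage_spec("ibutton_tape", 0.0100, 0.0170, 1.6),
    coverage_spec("ibutton_only", 0.0120, 0.0141, 2.6),
    coverage_spec("tape_only",    0.0020, 0.0050, 1.0),
    coverage_spec("bare",         0,      0,      1.0)
  )
}

#' Sensor type mounted by a coverage condition
#'
#' @param name Coverage name(s).
#' @return Sensor type character vector (`NA` for sensorless coverages).
#' @export
#' @examples
#' sensor_type_of(c("ibutton_only", "tape_only"))
sensor_type_of <- function(name) unname(COVERAGE_SENSOR[name])

SENSOR_TYPES <- c("custom", "grant", "ibutton", "embedded", "hygrometer")

#' Sensor measurement characteristics
#'
#' @param sensor_type One of `"custom"`, `"grant"`, `"ibutton"`, `"embedded"`,
#'   `"hygrometer"`.
#' @param resolution Quantization step of the logged value, degC (0 = none).
#'   iButtons self-log at 0.0625 degC; logger channels at 0.01 degC.
#' @param noise_sd Gaussian read-noise SD, degC.
#' @param true_gain,true_offset Linear instrument error of the raw reading
#'   (raw = gain * true + offset); both identity for a calibrated sensor.
#' @param response_time First-order sensor response time, s.
#'
#' @return A one-row tibble of class `sensor_spec`.
#' @seealso [default_sensors()]
#' @export
sensor_spec <- function(sensor_type,
                        resolution = 0.01,
                        noise_sd = 0.01,
                        true_gain = 1,
                        true_offset = 0,
                        response_time = 10) {
  sensor_type <- match.arg(sensor_type, SENSOR_TYPES)
  if (!is.finite(resolution) || resolution < 0 ||
      !is.finite(noise_sd) || noise_sd < 0) {
    abort("`resolution` and `noise_sd` must be finite and >= 0.",
          class = "thermoskin_validation_error")
  }
  out <- tibble::tibble(sensor_type = sensor_type, resolution = resolution,
                        noise_sd = noise_sd, true_gain = true_gain,
                        true_offset = true_offset,
                        response_time = response_time)
  class(out) <- c("sensor_spec", class(out))
  out
}

#' Default sensor specifications
#'
#' Logger-recorded thermistors (custom, Grant, embedded reference) resolve
#' 0.01 degC; iButtons self-log at 0.0625 degC with somewhat higher noise.
#'
#' @return A tibble, one [sensor_spec()] per row.
#' @export
default_sensors <- function() {
  dplyr::bind_rows(
    sensor_spec("custom",     resolution = 0.01,   noise_sd = 0.010,
                response_time = 10),
    sensor_spec("grant",      resolution = 0.01,   noise_sd = 0.010,
                response_time = 15),
    sensor_spec("ibutton",    resolution = 0.0625, noise_sd = 0.020,
                response_time = 60),
    sensor_spec("embedded",   resolution = 0.01,   noise_sd = 0.005,
                response_time = 5),
    sensor_spec("hygrometer", resolution = 0.1,    noise_sd = 0.5,
                response_time = 8)
  )
}

#' Rig run configuration
#'
#' Environmental and protocol settings of one rig run: five 30-min plate
#' temperature steps sampled every 10 s, beginning with the surface at the
#' environmental air temperature (zero gradient) and finishing with
#' surface-to-environment gradients of roughly 16 degC (0.5 m/s air velocity)
#' or 18 degC (0.2 m/s) using the same plate setpoints.
#'
#' @param ambient_temp Environmental air (= radiant) temperature, degC.
#' @param ambient_rh Environmental relative humidity, %.
#' @param air_velocity Air velocity over the surface, m/s (0.2 or 0.5 in the
#'   default design).
#' @param plate_setpoints Five nondecreasing plate temperatures, degC.
#' @param step_duration Duration of each plate step, s.
#' @param sample_interval Logging interval, s.
#' @param z1 Depth of the subsurface reference thermistor, m (< 1 mm).
#' @param z2 Depth of the second embedded thermistor, m.
#' @param seed Optional integer seed recorded with the run.
#'
#' @return A list of class `rig_config`.
#' @export
#' @examples
#' cfg <- rig_config(air_velocity = 0.5)
#' cfg$plate_setpoints
rig_config <- function(ambient_temp = 23.8,
                       ambient_rh = 42,
                       air_velocity = 0.2,
                       plate_setpoints = ambient_temp + c(0, 7, 14, 21, 28),
                       step_duration = 1800,
                       sample_interval = 10,
                       z1 = 0.25e-3,
                       z2 = 5e-3,
                       seed = NULL) {
  if (length(plate_setpoints) != 5 || is.unsorted(plate_setpoints)) {
    abort("`plate_setpoints` must be exactly 5 nondecreasing values.",
          class = "thermoskin_validation_error")
  }
  if (!(z1 > 0 && z2 > z1)) {
    abort("Depths must satisfy 0 < z1 < z2.",
          class = "thermoskin_validation_error")
  }
  if (step_duration %% sample_interval != 0) {
    abort("`step_duration` must be an integer multiple of `sample_interval`.",
          class = "thermoskin_validation_error")
  }
  structure(list(ambient_temp = ambient_temp, ambient_rh = ambient_rh,
                 air_velocity = air_velocity,
                 plate_setpoints = plate_setpoints,
                 step_duration = step_duration,
                 sample_interval = sample_interval,
                 z1 = z1, z2 = z2, seed = seed),
            class = "rig_config")
}
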