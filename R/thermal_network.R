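#' Surface heat-transfer coefficients
#'
#' Convection follows a flat-plate-style correlation `h_c = 15.65 * sqrt(v)`
#' (about 7 W m^-2 K^-1 at 0.2 m/s and 11 at 0.5 m/s); radiation is linearized
#' at the ambient temperature, `h_r = 4 * emissivity * sigma * T_amb^3`, which
#' keeps the whole network linear in temperature differences.
#'
#' @param air_velocity Air velocity, m/s.
#' @param emissivity Surface emissivity.
#' @param ambient_temp Ambient (air = radiant) temperature, degC.
#'
#' @return A one-row tibble with `h_c`, `h_r` and their sum `h` (W m^-2 K^-1).
#' @export
#' @examples
#' heat_transfer_coefficients(0.2)
#' heat_transfer_coefficients(0.5)
heat_transfer_coefficients <- function(air_velocity, emissivity = 0.90,
                                       ambient_temp = 23.8) {
  if (!is.finite(air_velocity) || air_velocity <= 0) {
    abort("`air_velocity` must be finite and > 0.",
          class = "thermoskin_validation_error")
  }
  h_c <- 15.65 * sqrt(air_velocity)
  h_r <- 4 * emissivity * SIGMA_SB * (ambient_temp + 273.15)^3
  tibble::tibble(h_c = h_c, h_r = h_r, h = h_c + h_r)
}

#' Solve the steady-state thermal network of the skin model
#'
#' The skin model is represented as two independent one-dimensional columns
#' driven by the plate temperature at the bottom and the environment at the
#' top.  The undisturbed column is plate -> slab conduction -> surface ->
#' boundary layer -> environment.  The disturbed column inserts the coverage:
#' plate -> slab -> surface -> contact resistance -> sensor node -> top
#' resistance -> boundary layer (conductance scaled by `area_factor`) ->
#' environment.  The in-slab temperature profile is strictly linear, so
#' subsurface temperatures at depths `z1`/`z2` follow from the surface value
#' and the heat flux.
#'
#' With added resistance above the surface the disturbed column carries less
#' flux, so its surface runs warmer than the bare surface; a strongly fin-like
#' coverage (`area_factor` >> 1) lowers the above-surface resistance and cools
#' the surface instead.
#'
#' @param material A [material_props()] row.
#' @param coverage A [coverage_spec()] row.
#' @param config A [rig_config()].
#' @param plate_temp Plate temperature(s), degC; vectorized.
#'
#' @return A tibble with one row per `plate_temp`: `plate_temp`,
#'   `surface_disturbed`, `surface_undisturbed`, `sensor_node`,
#'   `t_z1_disturbed`, `t_z2_disturbed`, `t_z1_undisturbed`,
#'   `t_z2_undisturbed`, `flux_disturbed`, `flux_undisturbed` (W m^-2).
#' @export
#' @examples
#' nodes <- solve_thermal_network(material_props(),
#'                                coverage_spec("tape_only", 0.002, 0.005),
#'                                rig_config(air_velocity = 0.2),
#'                                plate_temp = 45)
#' nodes$surface_disturbed - nodes$surface_undisturbed  # tape warms the surface
solve_thermal_network <- function(material, coverage, config, plate_temp) {
  stopifnot(inherits(material, "material_props"),
            inherits(coverage, "coverage_spec"),
            inherits(config, "rig_config"))
  if (any(!is.finite(plate_temp))) {
    abort("`plate_temp` must be finite.", class = "thermoskin_validation_error")
  }
  if (config$z2 >= material$thickness) {
    abort("`z2` must be smaller than the slab thickness.",
          class = "thermoskin_validation_error")
  }
  k <- material$conductivity
  r_slab <- material$thickness / k
  h <- heat_transfer_coefficients(config$air_velocity, material$emissivity,
                                  config$ambient_temp)$h
  ta <- config$ambient_temp

  # undisturbed column
  r_u <- r_slab + 1 / h
  q_u <- (plate_temp - ta) / r_u
  surf_u <- ta + q_u / h

  # disturbed column
  r_bound_d <- 1 / (coverage$area_factor * h)
  r_above <- coverage$contact_resistance + coverage$top_resistance + r_bound_d
  q_d <- (plate_temp - ta) / (r_slab + r_above)
  surf_d <- ta + q_d * r_above
  node <- ta + q_d * (coverage$top_resistance + r_bound_d)

  tibble::tibble(
    plate_temp = plate_temp,
    surface_disturbed = surf_d,
    surface_undisturbed = surf_u,
    sensor_node = node,
    t_z1_disturbed = surf_d + q_d * config$z1 / k,
    t_z2_disturbed = surf_d + q_d * config$z2 / k,
    t_z1_undisturbed = surf_u + q_u * config$z1 / k,
    t_z2_undisturbed = surf_u + q_u * config$z2 / k,
    flux_disturbed = q_d,
    flux_undisturbed = q_u
  )
}

#' Energy-balance residuals of a solved network
#'
#' Recomputes the flux across every series element of both columns from the
#' node temperatures and returns the largest node imbalance relative to the
#' column throughput flux.  At steady state the residual should be at numerical
#' round-off (< 1e-9).
#'
#' @param nodes Output of [solve_thermal_network()].
#' @param material,coverage,config The inputs used to produce `nodes`.
#'
#' @return Numeric vector of relative residuals, one per row of `nodes`.
#' @export
energy_balance_residual <- function(nodes, material, coverage, config) {
  k <- material$conductivity
  h <- heat_transfer_coefficients(config$air_velocity, material$emissivity,
                                  config$ambient_temp)$h
  ta <- config$ambient_temp
  r_slab <- material$thickness / k
  r_bound_d <- 1 / (coverage$area_factor * h)

  # elementwise fluxes, disturbed column
  q_slab_d <- (nodes$plate_temp - nodes$surface_disturbed) / r_slab
  q_bound_d <- (nodes$surface_disturbed - ta) /
    (coverage$contact_resistance + coverage$top_resistance + r_bound_d)
  q_node_d <- if (coverage$contact_resistance > 0) {
    (nodes$surface_disturbed - nodes$sensor_node) / coverage$contact_resistance
  } else {
    q_bound_d
  }
  # undisturbed column
  q_slab_u <- (nodes$plate_temp - nodes$surface_undisturbed) / r_slab
  q_bound_u <- (nodes$surface_undisturbed - ta) * h

  scale_d <- pmax(abs(nodes$flux_disturbed), 1)
  scale_u <- pmax(abs(nodes$flux_undisturbed), 1)
  pmax(abs(q_slab_d - q_bound_d) / scale_d,
       abs(q_node_d - q_bound_d) / scale_d,
       abs(q_slab_u - q_bound_u) / scale_u)
}
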