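SITE_BASE_TEMP <- c(chest = 33.2, arm = 32.2, thigh = 31.6, leg = 31.2)

# group-level skin temperature trajectory (deviation from site baseline, degC):
# stable rest, slight drop at exercise onset, rise through the fixed loads,
# decline through warm-down and recovery
TREND_KNOTS_MIN <- c(0, 36, 45, 48, 60, 75, 90, 95, 115, 135)
TREND_KNOTS_DEG <- c(0, 0.05, 0, -0.3, 0.5, 1.0, 0.7, 0.5, 0.1, -0.1)

#' Simulate a human-trial dataset
#'
#' Generates per-participant, per-site skin-temperature series for the three
#' sensor types (shared smooth physiological trend, participant and site
#' offsets, sensor-type offsets, read noise and quantization) and per-site
#' humidity/temperature series whose absolute vapor pressure exhibits a step
#' increase at an injected sweat-onset time during exercise.
#'
#' @param n_participants Number of participants.
#' @param protocol Phase table from [trial_protocol()].
#' @param sensors Sensor specification table, as [default_sensors()].
#' @param type_offsets Named systematic offsets of the sensor types, degC.
#' @param sweat_onset_min Injected sweat-onset times, minutes after exercise
#'   start: either a single value recycled to all participants, a vector of
#'   length `n_participants`, or `NULL` to draw from
#'   `Normal(onset_mean, onset_sd)` truncated at 1 min.
#' @param onset_mean,onset_sd Distribution of the onset when drawn, min.
#' @param vp_baseline Pre-exercise absolute vapor pressure at the skin, kPa.
#' @param vp_step Step increase of vapor pressure at sweat onset, kPa.
#' @param sample_interval Logging interval, s.
#' @param seed Integer seed.
#'
#' @return A list of class `trial_dataset`: `tsk` (tibble `participant`,
#'   `site`, `sensor_type`, `time_min`, `temp`), `humidity` (tibble
#'   `participant`, `site`, `time_min`, `temp`, `rh`), `onsets` (tibble of
#'   the injected onsets: `participant`, `onset_min`, `time_min`, `site`),
#'   `protocol`, and `exercise_start_min`.
#' @export
#' @examples
#' trial <- simulate_human_trial(n_participants = 2, seed = 7)
#' dplyr::glimpse(trial$tsk)
simulate_human_trial <- function(n_participants = 14,
                                 protocol = trial_protocol(),
                                 sensors = default_sensors(),
                                 type_offsets = c(custom = 0, grant = 0.10,
                                                  ibutton = 0.25),
                                 sweat_onset_min = NULL,
                                 onset_mean = 7.4, onset_sd = 1.6,
                                 vp_baseline = 1.6, vp_step = 0.8,
                                 sample_interval = 10,
                                 seed = 1L) {
  validate_periods(protocol$start_min, protocol$end_min)
  set.seed(seed)
  ex_start <- protocol$start_min[protocol$phase == "FL1"]
  rec_start <- protocol$start_min[protocol$phase == "recovery"]
  t_end <- max(protocol$end_min)
  t_min <- seq(0, t_end, by = sample_interval / 60)
  trend <- approx(TREND_KNOTS_MIN, TREND_KNOTS_DEG, xout = t_min,
                  rule = 2)$y

  if (is.null(sweat_onset_min)) {
    onset <- pmax(1, rnorm(n_participants, onset_mean, onset_sd))
  } else {
    onset <- rep_len(sweat_onset_min, n_participants)
  }
  trigger_site <- sample(TRIAL_SITES, n_participants, replace = TRUE)

  types <- names(type_offsets)
  spec_of <- function(type) sensors[sensors$sensor_type == type, ][1, ]

  tsk <- list(); humidity <- list(); onsets <- list()
  for (p in seq_len(n_participants)) {
    p_off <- rnorm(1, 0, 0.4)
    for (site in TRIAL_SITES) {
      s_off <- rnorm(1, 0, 0.15)
      truth <- SITE_BASE_TEMP[[site]] + trend + p_off + s_off
      for (ty in types) {
        sp <- spec_of(ty)
        obs <- quantize(truth + type_offsets[[ty]] +
                          rnorm(length(truth), 0, sp$noise_sd),
                        sp$resolution)
        tsk[[length(tsk) + 1]] <- tibble::tibble(
          participant = p, site = site, sensor_type = ty,
          time_min = t_min, temp = obs)
      }
      # humidity channel: vapor pressure steps up at the site's onset and
      # decays back toward baseline during recovery rest
      lag <- if (site == trigger_site[p]) 0 else stats::runif(1, 0.5, 3)
      onset_abs <- ex_start + onset[p] + lag
      vp0 <- vp_baseline + rnorm(1, 0, 0.05)
      vp <- rep(vp0, length(t_min))
      sweating <- t_min >= onset_abs
      vp[sweating] <- vp0 + vp_step
      rec <- t_min >= rec_start & sweating
      vp[rec] <- vp0 + vp_step * exp(-(t_min[rec] - rec_start) / 8)
      hy <- spec_of("hygrometer")
      temp_obs <- truth + 0.3 + rnorm(length(truth), 0, 0.05)
      svp <- vapor_pressure(temp_obs, 100)
      rh <- pmin(100, pmax(1, 100 * vp / svp))
      rh <- quantize(rh + rnorm(length(rh), 0, 0.1), hy$resolution)
      rh <- pmin(100, pmax(0, rh))
      humidity[[length(humidity) + 1]] <- tibble::tibble(
        participant = p, site = site, time_min = t_min,
        temp = round(temp_obs, 2), rh = rh)
    }
    onsets[[p]] <- tibble::tibble(participant = p, onset_min = onset[p],
                                  time_min = ex_start + onset[p],
                                  site = trigger_site[p])
  }
  structure(list(tsk = dplyr::bind_rows(tsk),
                 humidity = dplyr::bind_rows(humidity),
                 onsets = dplyr::bind_rows(onsets),
                 protocol = protocol,
                 exercise_start_min = ex_start),
            class = "trial_dataset")
}
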