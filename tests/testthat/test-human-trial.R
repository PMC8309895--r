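test_that("weighted-mean skin temperature is the 0.3/0.3/0.2/0.2 combination", {
  expect_equal(weighted_mean_tsk(33, 33, 33, 33), 33)
  expect_equal(weighted_mean_tsk(34, 33, 32, 31), 32.7)
  expect_equal(sum(c(0.3, 0.3, 0.2, 0.2)), 1)
  # shift equivariance
  expect_equal(weighted_mean_tsk(34 + 2, 33 + 2, 32 + 2, 31 + 2),
               32.7 + 2)
  # site order matters
  expect_false(weighted_mean_tsk(34, 33, 32, 31) ==
                 weighted_mean_tsk(31, 32, 33, 34))
  expect_error(weighted_mean_tsk(34, NA, 32, 31),
               class = "thermoskin_validation_error")
})

test_that("period means average half-open 3-min windows", {
  t <- seq(0, 135, by = 1 / 6)
  const <- tibble::tibble(time_min = t, value = 5)
  periods <- trial_periods(52)
  pm <- period_means(const, periods)
  expect_equal(nrow(pm), 7)
  expect_equal(pm$period, periods$period)
  expect_true(all(pm$mean == 5))

  ramp <- tibble::tibble(time_min = t, value = 30 + 0.05 * t)
  inside <- t >= 36 & t < 39
  expected <- 30 + 0.05 * mean(t[inside])  # linearity: value at mean time
  expect_equal(period_means(ramp, trial_periods(52))$mean[1], expected)

  bad <- tibble::tibble(period = "X", start_min = 140, end_min = 143)
  expect_error(period_means(const, bad), class = "thermoskin_period_error")
})

test_that("vapor pressure follows the Magnus form and its monotonicity", {
  expect_equal(vapor_pressure(25, 0), 0)
  expect_equal(vapor_pressure(20, 100),
               0.61094 * exp(17.625 * 20 / 263.04))  # 2.33358 kPa
  expect_equal(vapor_pressure(30, 50), vapor_pressure(30, 100) / 2)
  expect_error(vapor_pressure(30, 101), class = "thermoskin_validation_error")
  temps <- seq(15, 40, by = 5)
  expect_true(all(diff(vapor_pressure(temps, 60)) > 0))
})

make_vp_series <- function(onsets_min, step_kpa = 0.6, baseline = 1.5,
                           t_end = 90) {
  t <- seq(0, t_end, by = 1 / 6)
  purrr::map_dfr(names(onsets_min), function(site) {
    vp <- rep(baseline, length(t))
    on <- onsets_min[[site]]
    if (is.finite(on)) vp[t >= on] <- baseline + step_kpa
    tibble::tibble(site = site, time_min = t, vp = vp)
  })
}

test_that("sweat onset is recovered within one sample and below-threshold rises are ignored", {
  vp <- make_vp_series(c(chest = 50, arm = Inf, thigh = Inf, leg = Inf))
  on <- detect_sweat_onset(vp, exercise_start_min = 45)
  expect_equal(on$site, "chest")
  expect_lte(abs(on$time_min - 50), 1 / 6)

  small <- make_vp_series(c(chest = 50, arm = Inf, thigh = Inf, leg = Inf),
                          step_kpa = 0.4)
  expect_equal(nrow(detect_sweat_onset(small, 45)), 0)

  multi <- make_vp_series(c(chest = 52, arm = 48, thigh = Inf, leg = Inf))
  on2 <- detect_sweat_onset(multi, 45)
  expect_equal(on2$site, "arm")  # earliest of the sites wins
  expect_lte(abs(on2$time_min - 48), 1 / 6)
})

test_that("the onset detector is translation-equivariant", {
  for (delta in c(0, 3.5, 10)) {
    vp <- make_vp_series(c(chest = 50 + delta, arm = Inf,
                           thigh = Inf, leg = Inf))
    on <- detect_sweat_onset(vp, 45)
    expect_lte(abs(on$time_min - (50 + delta)), 1 / 6)
  }
})

test_that("a brief spike shorter than the sustain requirement is not an onset", {
  t <- seq(0, 90, by = 1 / 6)
  vp <- rep(1.5, length(t))
  vp[t >= 50 & t < 50.5] <- 2.2  # 30 s spike only
  df <- tibble::tibble(site = "chest", time_min = t, vp = vp)
  expect_equal(nrow(detect_sweat_onset(df, 45)), 0)
})

test_that("trial differences are antisymmetric and respect the sign convention", {
  vals <- tidyr::expand_grid(participant = 1:6,
                             sensor_type = c("custom", "grant", "ibutton"),
                             period = c("BR", "FL1"))
  set.seed(9)
  offs <- c(custom = 0, grant = 0.2, ibutton = -0.1)
  vals$value <- 32 + offs[vals$sensor_type] + rnorm(nrow(vals), 0, 0.05)
  d <- trial_intersensor_differences(vals)
  gc <- dplyr::filter(d, pair == "grant-custom")
  expect_lt(max(abs(gc$mean - 0.2)), 0.1)
  # iButton is cooler than grant -> negative differences (first listed cooler)
  ig <- dplyr::filter(d, pair == "ibutton-grant")
  expect_true(all(ig$mean < 0))
  # antisymmetry via relabelling the pair members
  swapped <- dplyr::mutate(vals, sensor_type = dplyr::recode(
    sensor_type, custom = "grant", grant = "custom"))
  d_sw <- trial_intersensor_differences(swapped)
  expect_equal(dplyr::filter(d_sw, pair == "grant-custom")$mean, -gc$mean)
})

test_that("participants missing a sensor type are excluded with a warning", {
  vals <- tidyr::expand_grid(participant = 1:3,
                             sensor_type = c("custom", "grant", "ibutton"),
                             period = "BR")
  vals$value <- 32
  vals <- vals[!(vals$participant == 2 & vals$sensor_type == "ibutton"), ]
  expect_warning(d <- trial_intersensor_differences(vals),
                 class = "thermoskin_participant_excluded")
  expect_true(all(d$n == 2))
})

test_that("injected sensor-type offsets are recovered within CI at nominal rate", {
  # Monte-Carlo on simulated period values: within-participant structure with
  # known type offsets, 500 repetitions
  offs <- c(custom = 0, grant = 0.2, ibutton = -0.1)
  true_diff <- c("grant-custom" = 0.2, "ibutton-custom" = -0.1,
                 "ibutton-grant" = -0.3)
  set.seed(123)
  hits <- 0L
  reps <- 500
  for (i in seq_len(reps)) {
    vals <- tidyr::expand_grid(participant = 1:14,
                               sensor_type = names(offs), period = "FL3")
    vals$value <- 32 + rnorm(14, 0, 0.4)[vals$participant] +
      offs[vals$sensor_type] + rnorm(nrow(vals), 0, 0.15)
    d <- trial_intersensor_differences(vals)
    ok <- all(d$ci_low <= true_diff[d$pair] & true_diff[d$pair] <= d$ci_high)
    hits <- hits + ok
  }
  # all three intervals jointly cover ~ 0.95^3 of the time at worst
  expect_gte(hits / reps, 0.85)
})

test_that("generator and analysis round-trip: null offsets give null differences", {
  trial <- simulate_human_trial(n_participants = 4,
                                type_offsets = c(custom = 0, grant = 0,
                                                 ibutton = 0),
                                sweat_onset_min = 7, seed = 31L)
  res <- analyze_human_trial(trial)
  expect_true(all(abs(res$differences$mean) < 0.1))
  # detected onsets match the injected minute-7 onset within one sample
  expect_true(all(abs(res$onsets$onset_min - 7) <= 1 / 6 + 1e-9))
  expect_equal(nrow(res$custom_group_means), 7)
})
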