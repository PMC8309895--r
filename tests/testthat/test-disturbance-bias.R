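make_states_row <- function(coverage, velocity, replicate, step, setpoint,
                            t_u_own, t_sen = NA_real_, t_d = NA_real_,
                            ambient = 23.8) {
  tibble::tibble(run_id = sprintf("%s_v%02.0f_r%d", coverage, 100 * velocity,
                                  replicate),
                 coverage = coverage, velocity = velocity,
                 replicate = replicate, step = step, setpoint = setpoint,
                 ambient = ambient, t_sen = t_sen,
                 t_d = if (all(is.na(t_d))) t_u_own else t_d, corr_d = 0,
                 t_u_own = t_u_own, corr_u = 0, qualified = TRUE)
}

test_that("pairing is by identity when a bare replicate exists", {
  states <- dplyr::bind_rows(
    make_states_row("bare", 0.2, 1, 1:2, c(30, 40), c(29.0, 37.0)),
    make_states_row("tape_only", 0.2, 1, 1:2, c(30, 40), c(29.3, 37.8)))
  paired <- match_undisturbed(states)
  expect_equal(paired$t_u, c(29.0, 37.0))
  expect_equal(paired$disturbance, c(0.3, 0.8))
})

test_that("missing bare replicates fall back to interpolation vs setpoint", {
  states <- dplyr::bind_rows(
    make_states_row("bare", 0.2, 1, 1:2, c(30, 40), c(29.0, 37.0)),
    make_states_row("tape_only", 0.2, 9, 1, 35, 33.5))
  paired <- match_undisturbed(states)
  expect_equal(paired$t_u, (29.0 + 37.0) / 2)  # midpoint of the bare values
})

test_that("a velocity without bare runs raises an unmatched error", {
  states <- dplyr::bind_rows(
    make_states_row("bare", 0.2, 1, 1, 30, 29.0),
    make_states_row("tape_only", 0.5, 1, 1, 30, 29.5))
  expect_error(match_undisturbed(states),
               class = "thermoskin_unmatched_error")
})

test_that("disturbance and bias are the printed signed differences", {
  expect_equal(compute_disturbance(31, 31), 0)
  expect_equal(compute_disturbance(33.3, 34.2), -0.9)  # un-taped iButton, 0.5 m/s
  expect_equal(compute_disturbance(31.4, 31.3), 0.1,   # custom + tape, 0.2 m/s
               tolerance = 1e-12)
  expect_equal(compute_bias(31, 31), 0)
  expect_equal(compute_bias(31.0, 33.3), -2.3)
  expect_equal(compute_bias(31.0, 31.3), -0.3)
})

test_that("mean/CI summaries follow the unadjusted t-interval arithmetic", {
  s <- summarize_mean_ci(1:5)
  expect_equal(s$mean, 3)
  expect_equal(c(s$ci_low, s$ci_high), c(1.036757, 4.963243),
               tolerance = 1e-6)
  same <- summarize_mean_ci(rep(2.5, 4))
  expect_equal(same$ci_low, same$ci_high)
  two <- summarize_mean_ci(c(0, 1))
  half <- qt(0.975, 1) * sd(c(0, 1)) / sqrt(2)
  expect_equal(two$ci_low, 0.5 - half)
  expect_error(summarize_mean_ci(3), class = "thermoskin_undefined_ci")
})

test_that("gradient fits detect exact proportionality and exact linearity", {
  g <- c(0, 4, 8, 12, 16)
  f <- fit_vs_gradient(-0.1 * g, g)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_error(fit_vs_gradient(c(1, 2), c(1, 2)),
               class = "thermoskin_insufficient_data")

  # noiseless simulated bias vs gradient is linear to machine precision
  cfg <- rig_config(air_velocity = 0.5)
  cov <- default_coverages()[2, ]
  class(cov) <- unique(c("coverage_spec", class(cov)))
  nodes <- solve_thermal_network(material_props(), cov, cfg,
                                 cfg$plate_setpoints)
  bias <- nodes$sensor_node - nodes$surface_disturbed
  grad <- nodes$surface_undisturbed - cfg$ambient_temp
  expect_gt(fit_vs_gradient(bias, grad)$r_squared, 1 - 1e-12)
})

test_that("fixed-temperature evaluation returns the anchored operating point", {
  paired <- make_anchored_paired(t_d_op = 33.3, t_u_op = 34.2)
  est <- evaluate_at_fixed_sensor_temp(paired, "bias_from_td")
  expect_equal(est$mean, -2.3, tolerance = 1e-9)
  expect_equal(est$ci_low, est$ci_high)  # identical replicates: zero width
  expect_equal(est$n, 5L)
})

test_that("replicate spread propagates through the t-interval", {
  vals <- c(-0.5, -0.45, -0.4, -0.35, -0.3)
  paired <- make_anchored_paired(t_d_op = 31.4, t_u_op = 31.3,
                                 rep_values = vals)
  est <- evaluate_at_fixed_sensor_temp(paired, "bias_from_td")
  expect_equal(est$mean, -0.4, tolerance = 1e-9)
  expect_equal(c(est$ci_low, est$ci_high), c(-0.498, -0.302),
               tolerance = 1e-3)
})

test_that("a single replicate gives a point estimate with undefined CI", {
  paired <- make_anchored_paired(t_d_op = 33.3, t_u_op = 34.2,
                                 replicates = 1)
  expect_warning(est <- evaluate_at_fixed_sensor_temp(paired, "bias_from_td"),
                 class = "thermoskin_undefined_ci_warning")
  expect_equal(est$mean, -2.3, tolerance = 1e-9)
  expect_true(is.na(est$ci_low))
})

test_that("known linear bias in the sensor reading is recovered exactly", {
  # generating line: bias = -0.05 - 0.12 * (t_sen - 31)
  t_sen <- c(25, 28, 31, 34, 37)
  paired <- purrr::map_dfr(1:3, function(r) {
    bias <- -0.05 - 0.12 * (t_sen - 31)
    tibble::tibble(coverage = "grant_tape", velocity = 0.2, replicate = r,
                   step = 1:5, t_sen = t_sen, t_d = t_sen - bias,
                   t_u = t_sen - bias, ambient = 23.8,
                   gradient = t_sen - 23.8,
                   disturbance = 0, bias_from_td = bias, bias_from_tu = bias)
  })
  est <- evaluate_at_fixed_sensor_temp(paired, "bias_from_tu")
  expect_equal(est$mean, -0.05, tolerance = 1e-9)
})
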