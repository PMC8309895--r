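test_that("a constant series yields exactly one window, starting at t = 0", {
  s <- tibble::tibble(time_s = seq(0, 20 * 60 - 5, by = 5), value = 25)
  w <- find_steady_windows(s)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_s, 0)
  expect_equal(w$reference_sd, 0)
})

test_that("a slow ramp never qualifies (SD of a uniform ramp exceeds the gate)", {
  slope <- 0.01 / 60  # degC per s
  s <- tibble::tibble(time_s = seq(0, 30 * 60, by = 5))
  s$value <- 20 + slope * s$time_s
  # discrete-uniform oracle for the in-window SD (sample variance of an
  # arithmetic grid of n points with spacing d is d^2 * n * (n + 1) / 12)
  expect_equal(sd(s$value[1:96]), slope * 5 * sqrt(96 * 97 / 12),
               tolerance = 1e-12)
  expect_gt(sd(s$value[1:96]), 0.007)
  expect_equal(nrow(find_steady_windows(s)), 0)
})

test_that("greedy selection matches a brute-force scan on a step-plateau series", {
  set.seed(11)
  t <- seq(0, 25 * 60 - 5, by = 5)
  truth <- ifelse(t < 10 * 60, 20 + 0.004 * (10 * 60 - t), 22)
  truth[t >= 10 * 60] <- 30
  x <- truth + rnorm(length(t), 0, 0.003)
  s <- tibble::tibble(time_s = t, value = x)
  w <- find_steady_windows(s)
  # brute force: earliest start whose 96-sample window has sd < 0.007
  ok <- vapply(seq_len(length(t) - 95),
               function(i) sd(x[i:(i + 95)]) < 0.007, logical(1))
  expect_equal(nrow(w), 1)
  expect_equal(w$start_s, t[which(ok)[1]])
  expect_gte(w$start_s, 10 * 60)  # inside the plateau
})

test_that("series shorter than one window yields an empty result", {
  s <- tibble::tibble(time_s = seq(0, 200, by = 5), value = 25)
  expect_equal(nrow(find_steady_windows(s)), 0)
})

test_that("calibration fits recover exact and noiseless linear sensor errors", {
  true <- c(15, 20, 25, 30, 35, 40)
  ident <- fit_calibration(true, true)
  expect_equal(ident$gain, 1)
  expect_equal(ident$offset, 0)
  fit <- fit_calibration(true, 1.02 * true + 0.5)
  expect_equal(fit$gain, 1.02, tolerance = 1e-9)
  expect_equal(fit$offset, 0.5, tolerance = 1e-9)
  expect_equal(apply_calibration(31.12, fit), (31.12 - 0.5) / 1.02)
  expect_equal(apply_calibration(true * 1.02 + 0.5, fit), true)
})

test_that("calibration error contracts are enforced", {
  expect_error(fit_calibration(25, 25), class = "thermoskin_insufficient_data")
  expect_error(fit_calibration(c(20, 30), c(25, 25)),
               class = "thermoskin_degenerate_fit")
  expect_warning(fit_calibration(c(20, 25), c(20, 25)),
                 class = "thermoskin_span_warning")
})

test_that("simulate -> fit -> apply round trip leaves only read noise", {
  sens <- dplyr::mutate(
    sensor_spec("custom", noise_sd = 0.01, true_gain = 1.03,
                true_offset = -0.4),
    sensor_id = "c1")
  cal <- simulate_calibration_run(sensors = sens, seed = 21L)
  fits <- calibrate_sensors(cal)
  expect_equal(fits$gain, 1.03, tolerance = 5e-3)
  expect_equal(fits$offset, -0.4, tolerance = 0.1)
  raw <- cal$sensors$value
  truth <- cal$truth$value[match(cal$sensors$time_s, cal$truth$time_s)]
  resid <- apply_calibration(raw, fits$fit[[1]]) - truth
  expect_lte(sd(resid), sqrt(0.01^2 + 0.01^2 / 12) * 1.1)

  # idempotence: refitting already-corrected data is the identity within noise
  corrected <- tibble::tibble(time_s = cal$sensors$time_s, sensor_id = "c1",
                              value = apply_calibration(raw, fits$fit[[1]]))
  refit <- calibrate_sensors(list(reference = cal$reference,
                                  sensors = corrected))
  expect_equal(refit$gain, 1, tolerance = 2e-3)
  expect_equal(refit$offset, 0, tolerance = 0.05)
})

test_that("tidy and glance expose the calibration parameters", {
  fit <- fit_calibration(c(15, 25, 35), c(15.2, 25.2, 35.2), "s1")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "offset"], 0.2, tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_windows, 3)
})
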