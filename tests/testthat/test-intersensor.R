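test_that("reference fits recover exact linear relations", {
  x <- c(24, 28, 32, 36, 40)
  ident <- fit_sensor_to_reference(x, x)
  expect_equal(ident$b0, 0, tolerance = 1e-12)
  expect_equal(ident$b1, 1, tolerance = 1e-12)
  expect_equal(ident$r_squared, 1)

  f <- fit_sensor_to_reference(x, 2 + 1.1 * x)
  expect_equal(f$b0, 2, tolerance = 1e-9)
  expect_equal(f$b1, 1.1, tolerance = 1e-9)
  expect_false(f$flag_low_r2)

  expect_error(fit_sensor_to_reference(c(30, 30, 30), c(29, 30, 31)),
               class = "thermoskin_degenerate_fit")
  expect_error(fit_sensor_to_reference(c(30, 31), c(30, 31)),
               class = "thermoskin_insufficient_data")
})

test_that("inverse prediction is the exact algebraic inverse", {
  f <- list(b0 = -2, b1 = 1.05)
  expect_equal(inverse_predict(f, 32), 34 / 1.05, tolerance = 1e-12)
  expect_error(inverse_predict(list(b0 = 1, b1 = 0), 30),
               class = "thermoskin_non_invertible")

  set.seed(42)
  for (i in 1:20) {
    fit <- fit_sensor_to_reference(sort(stats::runif(5, 20, 40)),
                                   stats::rnorm(5, 30, 3))
    x <- stats::runif(1, 20, 40)
    expect_equal(inverse_predict(fit, predict_reference(fit, x)), x,
                 tolerance = 1e-12)
  }
})

test_that("anchors are per-sensor predictions of the trial group means", {
  means <- tibble::tibble(period = paste0("P", 1:7),
                          mean = c(33, 32.5, 32.8, 33.4, 33.2, 32.6, 32.4))
  ident <- fit_sensor_to_reference(c(24, 32, 40), c(24, 32, 40))
  a <- compute_anchors(means, list(ident))
  expect_equal(a$y_prime, means$mean)
  expect_equal(a$period, means$period)  # order preserved, 7 in / 7 out

  shifted <- list(b0 = -2, b1 = 1.05)
  class(shifted) <- "sensor_ref_fit"
  a2 <- compute_anchors(tibble::tibble(period = "P1", mean = 33),
                        list(shifted))
  expect_equal(a2$y_prime, -2 + 1.05 * 33)  # 32.65

  # several custom fits: anchors average the per-sensor predictions
  a3 <- compute_anchors(tibble::tibble(period = "P1", mean = 33),
                        list(ident, shifted))
  expect_equal(a3$y_prime, (33 + 32.65) / 2)

  expect_error(compute_anchors(tibble::tibble(period = "P1", mean = NA),
                               list(ident)),
               class = "thermoskin_validation_error")
})

make_estimates <- function(offsets = c(custom = 0, grant = 0, ibutton = 0),
                           n_rep = 5, noise_sd = 0, seed = 1) {
  set.seed(seed)
  anchors <- tibble::tibble(period = paste0("P", 1:3),
                            y_prime = c(31, 33, 35))
  purrr::map_dfr(names(offsets), function(ty) {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      fit <- list(b0 = -offsets[[ty]] + rnorm(1, 0, noise_sd), b1 = 1)
      tibble::tibble(sensor_type = ty, replicate = r,
                     period = anchors$period,
                     x_prime = inverse_predict(fit, anchors$y_prime))
    })
  })
}

test_that("identical sensor types give zero differences; b0 shifts map to constant differences", {
  est <- make_estimates()
  d <- intersensor_differences(est)
  expect_true(all(d$mean == 0))
  expect_true(all(d$ci_low == 0 & d$ci_high == 0))

  # grant shifted +0.2 in b0 relative to custom with shared slope:
  # x' = (y - b0)/1, so grant - custom = -0.2 everywhere
  est2 <- make_estimates(offsets = c(custom = 0, grant = -0.2, ibutton = 0))
  d2 <- intersensor_differences(est2)
  gc <- dplyr::filter(d2, pair == "grant-custom")
  expect_equal(gc$mean, rep(-0.2, 3), tolerance = 1e-12)
})

test_that("a constant added to every sensor leaves differences unchanged", {
  x <- c(24, 28, 32, 36, 40)
  y <- 1 + 1.02 * x
  anchors <- tibble::tibble(period = "P1", y_prime = 33)
  base <- purrr::map_dfr(c("custom", "grant", "ibutton"), function(ty) {
    off <- c(custom = 0, grant = 0.15, ibutton = 0.3)[[ty]]
    purrr::map_dfr(1:2, function(r) {
      fit <- fit_sensor_to_reference(x + off, y)
      tibble::tibble(sensor_type = ty, replicate = r, period = "P1",
                     x_prime = inverse_predict(fit, anchors$y_prime))
    })
  })
  shifted <- purrr::map_dfr(c("custom", "grant", "ibutton"), function(ty) {
    off <- c(custom = 0, grant = 0.15, ibutton = 0.3)[[ty]]
    purrr::map_dfr(1:2, function(r) {
      fit <- fit_sensor_to_reference(x + off + 1.7, y)
      tibble::tibble(sensor_type = ty, replicate = r, period = "P1",
                     x_prime = inverse_predict(fit, anchors$y_prime))
    })
  })
  expect_equal(shifted$x_prime - base$x_prime,
               rep(1.7, nrow(base)), tolerance = 1e-9)
  expect_equal(intersensor_differences(base)$mean,
               intersensor_differences(shifted)$mean, tolerance = 1e-9)
})

test_that("unbalanced replicate counts are rejected", {
  est <- make_estimates()
  expect_error(intersensor_differences(est[-1, ]),
               class = "thermoskin_unbalanced_error")
})
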