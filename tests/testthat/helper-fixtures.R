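# Paired steady states whose chosen error form is exactly linear in the
# sensor temperature and passes through (t_sen_op, value at the operating
# point); used to exercise the fixed-sensor-temperature machinery.
make_anchored_paired <- function(t_d_op, t_u_op,
                                 t_sen_op = 31,
                                 coverage = "ibutton_only",
                                 velocity = 0.5,
                                 replicates = 5,
                                 slope_d = 1.1, slope_u = 1.15,
                                 ambient = 23.8,
                                 rep_values = NULL) {
  t_sen <- c(24, 27.5, 31, 34.5, 38)
  purrr::map_dfr(seq_len(replicates), function(r) {
    shift <- if (is.null(rep_values)) 0 else rep_values[r] - (t_sen_op - t_d_op)
    t_d <- t_d_op + slope_d * (t_sen - t_sen_op) - shift
    t_u <- t_u_op + slope_u * (t_sen - t_sen_op) - shift
    tibble::tibble(
      run_id = sprintf("%s_r%d", coverage, r),
      coverage = coverage, velocity = velocity, replicate = r,
      step = 1:5, setpoint = NA_real_, ambient = ambient,
      t_sen = t_sen, t_d = t_d, t_u = t_u,
      corr_d = 0, qualified = TRUE,
      gradient = t_u - ambient,
      disturbance = compute_disturbance(t_d, t_u),
      bias_from_td = compute_bias(t_sen, t_d),
      bias_from_tu = compute_bias(t_sen, t_u))
  })
}

# small noiseless sensor/config set for convergence tests
noiseless_sensors <- function() {
  s <- default_sensors()
  s$noise_sd <- 0
  s$resolution <- 0
  s
}
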