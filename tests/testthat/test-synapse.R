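# Single-synapse TCL: sawtooth protocol, threshold, per-cycle update and
# the sweep analyses.

test_that("sawtooth signal hits its branch endpoints and stays periodic", {
  p <- fix_protocol(A = 4, s_mean = 10, tau_f = 0.2, tau_s = 0.8)
  expect_equal(sawtooth_signal(p, 0), 10 - 2)
  expect_equal(sawtooth_signal(p, 0.2), 10 + 2)
  expect_equal(sawtooth_signal(p, 1 - 1e-9), 10 - 2, tolerance = 1e-6)
  t <- seq(0, 3, by = 0.01)
  expect_equal(sawtooth_signal(p, t), sawtooth_signal(p, t + 2))
  # continuity across the period boundary
  expect_lt(abs(sawtooth_signal(p, 0.9999) - sawtooth_signal(p, 1.0001)), 0.01)
})

test_that("threshold nonlinearity zeroes the dead band and is odd", {
  th <- 0.7
  expect_identical(threshold_linear(th / 2, th), 0)
  expect_identical(threshold_linear(2 * th, th), 2 * th)
  u <- seq(-3, 3, by = 0.1)
  expect_equal(threshold_linear(-u, th), -threshold_linear(u, th))
  expect_error(threshold_linear(1, -1))
})

test_that("per-cycle update vanishes without a threshold (zero-area kernel)", {
  cfg <- synapse_config(fix_biphasic(), theta_g = 0, epsilon = 1)
  for (A in c(0.5, 2, 10)) {
    dw <- weight_update_cycle(cfg, fix_protocol(A = A))
    # with linear g the periodic integral of u is I * integral(s) = 0
    expect_lt(abs(dw), 1e-6 * A)
  }
})

test_that("per-cycle update collapses when both ramps are super-threshold", {
  k <- fix_biphasic()
  theta <- 3
  cfg <- synapse_config(k, theta_g = theta, epsilon = 1)
  # A far above A_max = theta * tau_s: slow-ramp response exceeds theta too,
  # so fast and slow contributions cancel as with theta = 0
  dw <- weight_update_cycle(cfg, fix_protocol(A = 100))
  expect_lt(abs(dw), 0.02 * 100)
})

test_that("Eq-7 regime: update tracks amplitude with slope one", {
  k <- fix_biphasic(tau_K = 0.01)
  theta <- choose_threshold(k, tau_f = 0.1, tau_s = 1, A_abs_max = 10,
                            n_theta = 10L, n_amp = 12L, A_abs_min = 1)
  cfg <- synapse_config(k, theta_g = theta, epsilon = 1)
  amps <- 10^seq(0, 1, length.out = 9)
  sw <- amplitude_sweep(cfg, fix_protocol(), amps)
  gl <- glance(sw)
  expect_equal(gl$slope, 1, tolerance = 0.05)
  expect_lt(abs(gl$offset), 0.05 * max(amps))
  # a sizeable compliant window exists where the update tracks A pointwise
  expect_gte(dynamic_range(sw), 2)
})

test_that("update is odd in the amplitude at zero mean signal", {
  k <- fix_biphasic()
  cfg <- synapse_config(k, theta_g = 2, epsilon = 1)
  for (A in c(1, 5)) {
    up <- weight_update_cycle(cfg, fix_protocol(A = A))
    dn <- weight_update_cycle(cfg, fix_protocol(A = -A))
    expect_equal(dn, -up, tolerance = 1e-9)
  }
})

test_that("sweep is at periodic steady state: more warm-up changes nothing", {
  cfg <- synapse_config(fix_biphasic(), theta_g = 1.7, epsilon = 1)
  amps <- c(2.2, 4.1, 8.3)
  s2 <- amplitude_sweep(cfg, fix_protocol(), amps, n_warmup = 2L)
  s4 <- amplitude_sweep(cfg, fix_protocol(), amps, n_warmup = 4L)
  expect_equal(s2$delta_w_over_eps, s4$delta_w_over_eps, tolerance = 1e-9)
})

test_that("sub-threshold sweeps give zero updates and empty dynamic range", {
  cfg <- synapse_config(fix_biphasic(), theta_g = 50, epsilon = 1)
  sw <- amplitude_sweep(cfg, fix_protocol(), c(0.1, 0.2, 0.4))
  expect_true(all(abs(sw$delta_w_over_eps) < 1e-9))
  expect_identical(dynamic_range(sw), 0)
  expect_error(fit_offset(sw), "linear region")
})

test_that("dynamic range respects the timescale bound and grows with it", {
  k <- fix_biphasic(tau_K = 0.01)
  ranges <- vapply(c(3, 10, 30), function(ratio) {
    tau_s <- 0.1 * ratio
    th <- choose_threshold(k, 0.1, tau_s, A_abs_max = 10,
                           n_theta = 10L, n_amp = 12L)
    amps <- exp(seq(log(10 / (2 * ratio)), log(10), length.out = 18))
    sw <- amplitude_sweep(synapse_config(k, th, 1),
                          fix_protocol(tau_s = tau_s), amps)
    dynamic_range(sw)
  }, numeric(1))
  expect_true(all(ranges <= c(3, 10, 30) + 1e-9))
  expect_true(all(diff(ranges) >= 0))
})

test_that("predicted offset follows the small-area closed form", {
  expect_identical(predicted_offset(0.3, 0, 1, 5), 0)
  # hand evaluation: (0.1 * 0.2 / 2) * 50 = 0.5
  expect_equal(predicted_offset(0.1, 0.2, 20, 30), 0.5)
  expect_equal(predicted_offset(0.1, 0.2, -20, -30),
               -predicted_offset(0.1, 0.2, 20, 30))
})

test_that("measured sweep offset matches the non-zero-area prediction", {
  tau_K <- 0.001; tau_f <- 0.1; tau_s <- 4; sbar <- 25
  for (I in c(0.2)) {
    k <- make_biphasic_kernel(tau_K, I, dt = tau_K / 20)
    lo <- I * (sbar + 20) + 40 / tau_s
    hi <- 2 / tau_f + I * (sbar - 1)
    theta <- sqrt(lo * hi)
    cfg <- synapse_config(k, theta_g = theta, epsilon = 1)
    tmpl <- sawtooth_protocol(1, sbar, tau_f, tau_s, dt = tau_K / 20)
    amps <- exp(seq(log(2), log(40), length.out = 12))
    off <- fit_offset(amplitude_sweep(cfg, tmpl, amps))
    expect_equal(off, predicted_offset(tau_f, I, sbar, sbar),
                 tolerance = 0.1)
  }
})

test_that("chosen threshold separates the two ramp plateaus and scales", {
  k <- fix_biphasic(tau_K = 0.01)
  th <- choose_threshold(k, tau_f = 0.1, tau_s = 1, A_abs_max = 10,
                         n_theta = 10L, n_amp = 12L, A_abs_min = 1)
  # plateau levels at the geometric mid of the operating range
  # (|u| = M1 * A / tau): the threshold must separate slow from fast
  A_mid <- sqrt(1 * 10)
  expect_gt(th, k$moment1 * A_mid / 1)    # above the slow plateau
  expect_lt(th, k$moment1 * A_mid / 0.1)  # below the fast plateau
  # doubling all amplitudes doubles the chosen threshold (linear system)
  th2 <- choose_threshold(k, tau_f = 0.1, tau_s = 1, A_abs_max = 20,
                          n_theta = 10L, n_amp = 12L, A_abs_min = 2)
  expect_equal(th2 / th, 2, tolerance = 1e-9)
})

test_that("sweep tidiers and CSV export expose the contract columns", {
  cfg <- synapse_config(fix_biphasic(), theta_g = 2, epsilon = 1)
  sw <- amplitude_sweep(cfg, fix_protocol(), c(2, 3, 4.5, 6))
  td <- tidy(sw)
  expect_named(td, c("amplitude", "delta_w_over_eps", "linear_region",
                     "compliant"))
  expect_s3_class(glance(sw), "tbl_df")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_sweep_csv(sw, csv)
  df <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(df, c("A", "delta_w_over_eps"))
  expect_equal(df$A, sw$amplitude)
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})
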