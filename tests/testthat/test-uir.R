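test_that("step onsets are found at the 50% crossing", {
  st <- make_step(1000, 10, 5)
  on <- detect_step_onsets(st)
  expect_lt(abs(on - 5), 1 / 1000)

  sq <- make_square_calibration(200, 8, n_cycles = 3)
  expect_length(detect_step_onsets(sq, min_separation_s = 2), 3)
  # the square starts low and ends high: one fewer falling edge
  falling <- detect_step_onsets(sq, polarity = "falling",
                                min_separation_s = 2)
  expect_length(falling, 2)
  expect_error(detect_step_onsets(time_series(rep(0, 100), 10)), )
})

test_that("onset detection is noise-robust at SNR 100", {
  rec <- simulate_recording(make_step(1000, 30, 5), default_chain())
  errs <- vapply(1:100, function(s) {
    noisy <- add_noise(rec, noise_spec(100, seed = s))
    abs(detect_step_onsets(noisy)[1] - 5)
  }, 1)
  expect_lt(max(errs), 2 / 1000)
})

test_that("step averaging subtracts baseline and reduces noise variance", {
  rec <- simulate_recording(make_square_calibration(200, 10, n_cycles = 4),
                            default_chain())
  on <- detect_step_onsets(rec, min_separation_s = 5)
  avg <- extract_and_average_steps(rec, on, pre_s = 1, post_s = 4,
                                   n_average = 3)
  # periodic steady state: averaging identical repeated segments
  # returns any one segment (first cycle excluded: startup differs)
  avg2 <- extract_and_average_steps(rec, on[2:4], pre_s = 1, post_s = 4,
                                    n_average = 3)
  one2 <- extract_and_average_steps(rec, on[2], pre_s = 1, post_s = 4,
                                    n_average = 1)
  expect_equal(avg2$samples, one2$samples, tolerance = 1e-3)
  one <- extract_and_average_steps(rec, on[1], pre_s = 1, post_s = 4,
                                   n_average = 1)
  expect_equal(formals(extract_and_average_steps)$n_average, 3L)
  expect_error(
    extract_and_average_steps(rec, on[1], pre_s = 1, post_s = 4,
                              n_average = 3),
    "insufficient")

  # noise variance of a 3-average is ~1/3 of a single segment
  resid_var <- vapply(1:30, function(s) {
    noisy <- add_noise(rec, noise_spec(100, seed = s))
    a3 <- extract_and_average_steps(noisy, on, 1, 4, 3)
    c(stats::var(a3$samples - avg$samples))
  }, 1)
  one_var <- vapply(1:30, function(s) {
    noisy <- add_noise(rec, noise_spec(100, seed = s))
    a1 <- extract_and_average_steps(noisy, on[1], 1, 4, 1)
    c(stats::var(a1$samples - one$samples))
  }, 1)
  expect_equal(mean(resid_var) / mean(one_var), 1 / 3, tolerance = 0.2)
})

test_that("polynomial fit nests lower orders and captures an exponential", {
  # cubic data, order-9 fit: residual at numerical noise level
  t <- (0:499) / 100
  cub <- time_series(1 + 2 * t - 0.3 * t^3, 100)
  fit <- fit_step_response(cub, order = 9, fit_window_s = c(0, 4.99))
  expect_lt(fit$residual_rms, 1e-9 * max(abs(cub$samples)))

  # exp(-t/tau), tau = 1.59 s, over [0, 5 tau] at 1000 samples/s
  tau <- 1.59
  te <- (0:(5 * tau * 1000)) / 1000
  ex <- time_series(exp(-te / tau), 1000)
  fe <- fit_step_response(ex, order = 9, fit_window_s = c(0, 5 * tau))
  err <- eval_step_fit(fe, te) - exp(-te / tau)
  expect_lt(max(abs(err)), 0.01)

  # order 0 on constant data returns the constant
  cst <- time_series(rep(2.5, 50), 10)
  f0 <- fit_step_response(cst, order = 0, fit_window_s = c(0, 4.9))
  expect_equal(eval_step_fit(f0, 2), 2.5)

  expect_error(fit_step_response(cub, order = 9, fit_window_s = c(0, 0.05)),
               "under-determined")
})

test_that("differentiating an exponential fit recovers its derivative", {
  tau <- 1.59
  te <- (0:(5 * tau * 1000)) / 1000
  fe <- fit_step_response(time_series(exp(-te / tau), 1000), order = 9,
                          fit_window_s = c(0, 5 * tau))
  uir <- differentiate_fit(fe)
  # interior of the window: h ~ -(1/tau) exp(-t/tau) within 2%
  idx <- seq(round(0.1 * length(uir$h)), round(0.8 * length(uir$h)))
  t_h <- (idx - 1) / 1000
  expect_lt(max(abs(uir$h[idx] - (-1 / tau) * exp(-t_h / tau))),
            0.02 * (1 / tau))
  # the initial impulse tap dominates a high-pass-style response
  expect_equal(which.max(abs(uir$h)), 1L)
})

test_that("a constant step response yields a degenerate UIR", {
  cst <- time_series(rep(0, 2000), 100)
  f <- fit_step_response(cst, order = 3, fit_window_s = c(0, 19))
  u <- differentiate_fit(f)
  expect_true(u$degenerate)
  expect_lt(max(abs(u$h)), 1e-9)
})

test_that("fundamental-theorem round trip: fit of cumsum(h)/rate recovers h", {
  rate <- 100
  t <- (0:999) / rate
  h <- exp(-t / 2)                      # smooth, h[1] != 0
  step <- time_series(cumsum(h) / rate, rate)
  fit <- fit_step_response(step, order = 9, fit_window_s = c(0, 9.99))
  u <- differentiate_fit(fit)
  m <- min(length(u$h), length(h))
  rel_rms <- sqrt(mean((u$h[seq_len(m)] - h[seq_len(m)])^2)) /
    sqrt(mean(h[seq_len(m)]^2))
  expect_lt(rel_rms, 0.03)
})

test_that("characterize_uir passes its self-check on the simulated chain", {
  uir <- uir_fixture(1000)
  expect_equal(uir$source, "measured_step")
  expect_lt(abs(uir$selfcheck$slope_per_s), 0.01)
  expect_equal(which.max(abs(uir$h)), 1L)
  # UIR duration matches the fit window
  expect_equal(length(uir$h) / uir$rate,
               diff(uir$fit$fit_window_s), tolerance = 0.01)
})

test_that("calibration-square UIR agrees with the measured-step UIR", {
  cal <- simulate_recording(make_square_calibration(1000, 30, n_cycles = 3),
                            default_chain())
  u_cal <- characterize_uir(cal, "calibration_square", min_separation_s = 5)
  u_step <- uir_fixture(1000)
  m <- min(length(u_cal$h), length(u_step$h))
  rel <- sqrt(mean((u_cal$h[1:m] - u_step$h[1:m])^2)) /
    sqrt(mean(u_step$h[1:m]^2))
  expect_lt(rel, 0.05)
  expect_lt(u_cal$selfcheck$flatness, 0.1)
})

test_that("an allpass system characterizes to a discrete delta", {
  chain <- recording_chain(filters = list(filter_spec("allpass")))
  rec <- simulate_recording(make_step(200, 30, 5), chain)
  u <- characterize_uir(rec, "measured_step")
  y <- make_mixed_sine(200, 30, freqs_hz = c(0.5, 3), amps = c(1, 0.3))
  x <- deconvolve(y, u)
  expect_lt(max(abs(x$samples - y$samples)), 1e-6)
})

test_that("a UIR from a noisy step still reconstructs a clean double-step", {
  rec <- add_noise(simulate_recording(make_step(1000, 30, 5),
                                      default_chain()),
                   noise_spec(100, seed = 42))
  u <- characterize_uir(rec, "measured_step")
  ds <- double_step_fixture(1000)
  y <- simulate_recording(ds, default_chain())
  x <- deconvolve(zero_mean(y), u)
  expect_gte(stats::cor(x$samples, ds$samples), 0.99)
})

test_that("UIR models survive a JSON round trip and rate re-derivation", {
  u <- uir_fixture(1000)
  path <- withr::local_tempfile(fileext = ".json")
  write_uir(u, path)
  u2 <- read_uir(path)
  expect_equal(u2$h, u$h, tolerance = 1e-10)
  expect_equal(u2$norm, u$norm, tolerance = 1e-10)
  u256 <- uir_at_rate(u, 256)
  expect_equal(u256$rate, 256)
  expect_equal(length(u256$h) / 256, length(u$h) / 1000, tolerance = 0.02)
  expect_error(uir_at_rate(uir_model(c(1, -0.5), 100), 50), "fit")
})
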