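test_that("deconvolution by a delta or scalar is exact", {
  y <- time_series(c(2, 4, 6), 10)
  expect_equal(deconvolve(y, uir_model(1, 10))$samples, c(2, 4, 6))
  expect_equal(deconvolve(y, uir_model(2, 10))$samples, c(1, 2, 3))
  expect_error(deconvolve(y, uir_model(c(0, 1), 10)), "unstable")
})

test_that("deconvolve inverts a forward convolution (double-step oracle)", {
  uir <- uir_fixture(1000)
  h_diff <- uir$h / 1000                 # discrete convolution kernel
  ds <- double_step_fixture(1000)
  y <- stats::convolve(c(ds$samples, numeric(length(h_diff) - 1)),
                       rev(h_diff), type = "open")[seq_along(ds$samples)]
  yts <- time_series(as.numeric(y), 1000)
  x <- deconvolve(yts, uir)
  expect_gte(stats::cor(x$samples, ds$samples), 0.999)
  # plateaus are restored flat
  p1 <- x$samples[11001:19000]
  expect_lt(max(p1) - min(p1), 0.05)
})

test_that("deconvolve matches the brute-force triangular solve", {
  set.seed(99)
  worst <- 0
  for (i in 1:100) {
    n <- sample(20:256, 1)
    m <- sample(2:min(12, n - 1), 1)
    # impulse-dominated kernel (|h1| > sum|rest|) so the inverse
    # recursion is numerically stable, as for physical high-pass UIRs
    h <- stats::rnorm(m)
    h[-1] <- 0.8 * abs(h[1]) * h[-1] / sum(abs(h[-1]))
    x <- stats::rnorm(n)
    y <- stats::convolve(c(x, numeric(m - 1)), rev(h),
                         type = "open")[seq_len(n)]
    q <- deconvolve(time_series(y, 1), uir_model(h, 1))
    k <- attr(q, "n_valid")
    ref <- toeplitz_deconv(y, h)
    worst <- max(worst, max(abs(q$samples[seq_len(k)] - ref)) /
                   max(abs(ref)))
  }
  expect_lt(worst, 1e-8)
})

test_that("convolving the quotient reproduces the recording", {
  uir <- uir_fixture(500)
  ds <- double_step_fixture(500)
  y <- simulate_recording(ds, default_chain())
  x <- deconvolve(zero_mean(y), uir)
  k <- attr(x, "n_valid")
  back <- stats::convolve(c(x$samples[seq_len(k)] / uir$norm,
                            numeric(length(uir$h) - 1)),
                          rev(uir$h), type = "open")[seq_len(k)]
  target <- zero_mean(y)$samples[seq_len(k)]
  expect_lt(max(abs(back - target)), 1e-6 * max(abs(target)))
})

test_that("drift frequency and minimum length follow the printed rules", {
  expect_equal(drift_frequency(600), 1 / 1200)
  expect_equal(drift_frequency(100), 0.005)
  expect_equal(drift_frequency(1), 0.5)
  expect_error(drift_frequency(0), "positive")
  expect_equal(min_length_for(0.005), 600)
  expect_equal(min_length_for(0.01), 300)
  expect_equal(min_length_for(1, min_periods = 3), 3)
  expect_error(min_length_for(-1), "positive")
})

test_that("remove_drift attenuates per the analytic magnitude", {
  cfg <- inverse_filter_config()
  x <- time_series(sin(2 * pi * 0.05 * (0:(1200 * 5 - 1)) / 5), 5)
  y <- remove_drift(x, cfg)
  spec <- filter_spec("butterworth_highpass", 2, 0.005)
  expected <- analytic_attenuation(spec, 0.05)^2  # forward-backward
  amp <- max(y$samples[2000:5000])
  expect_equal(amp, expected, tolerance = 0.02)
  expect_gt(expected, 0.99)

  # a linear ramp (one epoch of triangular drift) is strongly suppressed
  ramp <- time_series(seq(0, 1, length.out = 1200 * 5), 5)
  yr <- remove_drift(ramp, cfg)
  expect_lt(max(abs(yr$samples)), diff(range(ramp$samples)) / 10)

  cst <- time_series(rep(3, 1200 * 5), 5)
  expect_lt(max(abs(remove_drift(cst, cfg)$samples)), 1e-6)

  short <- time_series(stats::rnorm(100), 5)
  expect_warning(remove_drift(short, cfg), "3 periods")
})

test_that("inverse_filter enforces the minimum-length rule", {
  uir <- uir_fixture(1000)
  y <- simulate_recording(double_step_fixture(1000), default_chain())
  expect_error(inverse_filter(y, uir, inverse_filter_config()),
               "600 s")
  cfg <- inverse_filter_config(f_low_hz = 0.05)
  xf <- suppressWarnings(inverse_filter(y, uir, cfg))
  expect_equal(length(xf), length(y))
  log <- attr(xf, "log")
  expect_equal(log$epoch_length_s, 60)
  expect_equal(log$predicted_drift_hz, 1 / 120)
})

test_that("inverse_filter is linear", {
  uir <- uir_fixture(100)
  cfg <- inverse_filter_config(f_low_hz = 0.05)
  y1 <- simulate_recording(double_step_fixture(100), default_chain())
  y2 <- simulate_recording(
    make_mixed_sine(100, 60, freqs_hz = c(0.05, 2), amps = c(1, 0.4)),
    default_chain())
  ya <- time_series(2 * y1$samples + 3 * y2$samples, 100)
  fa <- suppressWarnings(inverse_filter(ya, uir, cfg))
  f1 <- suppressWarnings(inverse_filter(y1, uir, cfg))
  f2 <- suppressWarnings(inverse_filter(y2, uir, cfg))
  lin <- 2 * f1$samples + 3 * f2$samples
  expect_lt(max(abs(fa$samples - lin)), 1e-8 * max(abs(lin)))
})

test_that("inverse filtering an allpass recording returns the input", {
  chain <- recording_chain(filters = list(filter_spec("allpass")))
  rec <- simulate_recording(make_step(200, 30, 5), chain)
  u <- characterize_uir(rec, "measured_step")
  x <- make_mixed_sine(200, 700, freqs_hz = c(0.05, 1), amps = c(1, 0.5))
  xf <- inverse_filter(simulate_recording(x, chain), u,
                       inverse_filter_config())
  # differences confined to below the drift cutoff
  expect_gt(stats::cor(xf$samples, zero_mean(x)$samples), 0.999)
})

test_that("chunked inverse filtering agrees with the whole-signal result", {
  rate <- 50
  uir <- uir_fixture(rate)
  inp <- make_mixed_sine(rate, 1800)
  y <- simulate_recording(inp, default_chain())
  cfg <- inverse_filter_config(chunk_len_s = 600, chunk_overlap_s = 120)
  whole <- suppressWarnings(inverse_filter(y, uir, cfg))
  chunked <- suppressWarnings(chunked_inverse_filter(y, uir, cfg))
  i <- (100 * rate):(1700 * rate)
  dev <- sqrt(mean((chunked$samples[i] - whole$samples[i])^2)) /
    sqrt(mean(whole$samples[i]^2))
  expect_lt(dev, 0.05)

  # a single chunk covering the signal reduces to inverse_filter
  cfg1 <- inverse_filter_config(chunk_len_s = 1800, chunk_overlap_s = 120)
  one <- suppressWarnings(chunked_inverse_filter(y, uir, cfg1))
  expect_equal(one$samples, whole$samples)

  bad <- inverse_filter_config(chunk_len_s = 600, chunk_overlap_s = 10)
  expect_error(suppressWarnings(chunked_inverse_filter(y, uir, bad)),
               "overlap")
})
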