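#' Gaussian noise specification
#'
#' Noise level is expressed as a linear signal-to-noise ratio: the ratio
#' of signal variance to noise variance.  `Inf` means no noise.
#'
#' @param snr_linear Signal variance / noise variance, `> 0` (may be `Inf`).
#' @param seed Integer seed so noisy fixtures are reproducible.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr_linear = Inf, seed = 1L) {
  if (!is.numeric(snr_linear) || length(snr_linear) != 1L ||
      is.na(snr_linear) || snr_linear <= 0) {
    stop("snr_linear must be a single positive number (or Inf)",
         call. = FALSE)
  }
  structure(list(snr_linear = as.numeric(snr_linear),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Convert an SNR in dB to the linear variance ratio
#' @param snr_db SNR in decibels.
#' @return Linear variance ratio `10^(snr_db/10)`.
#' @export
snr_db_to_linear <- function(snr_db) 10^(snr_db / 10)

#' Step function
#'
#' @param rate Samples/s.
#' @param duration_s Total duration in seconds.
#' @param step_time_s Time of the step, in `[0, duration_s)`; the sample
#'   at `step_time_s` is already at the post-step level.
#' @param amplitude Step height.
#' @param baseline Pre-step level.
#' @return A [time_series()].
#' @export
make_step <- function(rate, duration_s, step_time_s,
                      amplitude = 1, baseline = 0) {
  if (step_time_s < 0 || step_time_s >= duration_s) {
    stop("step_time_s must lie in [0, duration_s)", call. = FALSE)
  }
  t <- (seq_len(round(rate * duration_s)) - 1) / rate
  x <- baseline + amplitude * (t >= step_time_s - 1e-12)
  time_series(x, rate = rate, label = "step")
}

#' Double-step (two-pulse) test function
#'
#' The test input used to verify a characterized UIR: two rectangular
#' pulses of equal amplitude on a zero baseline.
#'
#' @param rate Samples/s.
#' @param duration_s Total duration.
#' @param on1,off1,on2,off2 Pulse edges in seconds,
#'   `0 <= on1 < off1 <= on2 < off2 <= duration_s` (half-open intervals).
#' @param amplitude Pulse height.
#' @return A [time_series()].
#' @export
make_double_step <- function(rate, duration_s, on1, off1, on2, off2,
                             amplitude = 1) {
  ok <- on1 >= 0 && on1 <= off1 && off1 <= on2 && on2 <= off2 &&
    off2 <= duration_s
  if (!ok) {
    stop("pulse intervals must satisfy 0 <= on1 <= off1 <= on2 <= off2 <= duration",
         call. = FALSE)
  }
  t <- (seq_len(round(rate * duration_s)) - 1) / rate
  eps <- 1e-12
  x <- amplitude * ((t >= on1 - eps & t < off1 - eps) |
                      (t >= on2 - eps & t < off2 - eps))
  time_series(x, rate = rate, label = "double_step")
}

#' Step with a sine overlay
#'
#' A 10 Hz oscillation riding on top of a step: checks that inverse
#' filtering restores the DC shift while leaving frequencies well above
#' the high-pass cutoff untouched.
#'
#' @inheritParams make_step
#' @param sine_freq_hz Overlay frequency, default 10 Hz; must be below
#'   Nyquist.
#' @param sine_amp Overlay amplitude.
#' @return A [time_series()].
#' @export
make_step_with_sine <- function(rate, duration_s, step_time_s,
                                amplitude = 1, baseline = 0,
                                sine_freq_hz = 10, sine_amp = 0.25) {
  if (sine_freq_hz >= rate / 2) {
    stop("sine_freq_hz must be below the Nyquist frequency", call. = FALSE)
  }
  st <- make_step(rate, duration_s, step_time_s, amplitude, baseline)
  t <- ts_times(st)
  st$samples <- st$samples + sine_amp * sin(2 * pi * sine_freq_hz * t)
  st$label <- "step_plus_sine"
  st
}

#' Default mixed-sine component frequencies (Hz)
#'
#' Eight components spanning 0.01-10 Hz, straddling a 0.1 Hz high-pass
#' cutoff so that three components are strongly attenuated by an
#' AC-coupled recording chain and the rest pass.
#' @export
MIXED_SINE_FREQS_HZ <- c(0.01, 0.05, 0.07, 0.15, 0.2, 1, 6, 10)

#' Mixed-sine test function
#'
#' @param rate Samples/s.
#' @param duration_s Duration; at least `3 / min(freqs_hz)` is advisable
#'   (see [min_length_for()]).
#' @param freqs_hz Component frequencies, all below Nyquist.
#' @param amps,phases_rad Component amplitudes and phases; recycled
#'   scalars allowed.
#' @return A [time_series()] equal to
#'   `sum_k amps[k] * sin(2*pi*freqs_hz[k]*t + phases_rad[k])`.
#' @export
make_mixed_sine <- function(rate, duration_s,
                            freqs_hz = MIXED_SINE_FREQS_HZ,
                            amps = 1, phases_rad = 0) {
  k <- length(freqs_hz)
  if (length(amps) == 1L) amps <- rep(amps, k)
  if (length(phases_rad) == 1L) phases_rad <- rep(phases_rad, k)
  if (length(amps) != k || length(phases_rad) != k) {
    stop("freqs_hz, amps and phases_rad must have equal length",
         call. = FALSE)
  }
  if (any(freqs_hz >= rate / 2)) {
    stop("all component frequencies must be below Nyquist", call. = FALSE)
  }
  t <- (seq_len(round(rate * duration_s)) - 1) / rate
  x <- numeric(length(t))
  for (i in seq_len(k)) {
    x <- x + amps[i] * sin(2 * pi * freqs_hz[i] * t + phases_rad[i])
  }
  time_series(x, rate = rate, label = "mixed_sine")
}

#' Square-wave calibration signal
#'
#' Clinical EEG systems expose a square-wave calibration output; because
#' a square wave is a series of steps, it can stand in for a dedicated
#' step input when characterizing the system's UIR.  Three or more
#' cycles are required so that three step responses can be averaged.
#'
#' @param rate Samples/s.
#' @param period_s Period of one cycle.
#' @param amplitude High level (low level is 0).
#' @param n_cycles Number of full cycles, `>= 1` (default 3).
#' @return A [time_series()] starting at the low level.
#' @export
make_square_calibration <- function(rate, period_s, amplitude = 1,
                                    n_cycles = 3L) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  spp <- round(rate * period_s)
  half <- round(spp / 2)
  one <- c(rep(0, spp - half), rep(amplitude, half))
  time_series(rep(one, n_cycles), rate = rate, label = "calibration_square")
}

#' Add seeded Gaussian noise at a prescribed SNR
#'
#' @param ts A [time_series()] with nonzero variance (when SNR finite).
#' @param noise A [noise_spec()].
#' @return `ts` plus zero-mean Gaussian noise with variance
#'   `var(ts) / snr_linear`; identical for identical seeds.
#' @export
add_noise <- function(ts, noise) {
  stopifnot_time_series(ts)
  if (!inherits(noise, "noise_spec")) stop("need a noise_spec", call. = FALSE)
  if (is.infinite(noise$snr_linear)) return(ts)
  v <- stats::var(ts$samples)
  if (v <= 0) {
    stop("cannot set a finite SNR on a zero-variance signal", call. = FALSE)
  }
  sd_n <- sqrt(v / noise$snr_linear)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(noise$seed)
  ts$samples <- ts$samples + stats::rnorm(length(ts$samples), sd = sd_n)
  ts
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Surrogate seizure with DC shift and spreading depolarization
#'
#' A synthetic stand-in for a DC-amplifier seizure recording: baseline
#' noise, a smooth ramped DC shift that begins just before seizure
#' onset and persists through the seizure, a band-limited oscillatory
#' burst during the seizure, and a slow biphasic post-ictal wave
#' emulating spreading depolarization.  Ground-truth components are
#' returned separately so reconstructions can be validated against them.
#'
#' @param rate Samples/s.
#' @param duration_s Total duration.
#' @param onset_s,offset_s Seizure window `[onset, offset)`,
#'   `0 < onset < offset < duration`.
#' @param dc_shift_amp Amplitude of the ictal DC shift (negative for the
#'   downward shifts typical of seizure onset zones).
#' @param osc_freq_hz Centre frequency of the ictal oscillatory burst.
#' @param osc_amp Burst amplitude.
#' @param sd_wave_amp Amplitude of the post-ictal slow wave.
#' @param sd_wave_tau_s Time constant of the post-ictal wave.
#' @param noise_sd Standard deviation of the additive baseline noise.
#' @param seed Integer seed.
#' @return A list with `signal` (the composite [time_series()]) and
#'   `components` (list of time_series: `dc_shift`, `oscillation`,
#'   `sd_wave`, `noise`).
#' @export
make_surrogate_seizure <- function(rate, duration_s, onset_s, offset_s,
                                   dc_shift_amp = -1, osc_freq_hz = 8,
                                   osc_amp = 0.5, sd_wave_amp = 0.8,
                                   sd_wave_tau_s = 20, noise_sd = 0.02,
                                   seed = 1L) {
  if (!(0 < onset_s && onset_s < offset_s && offset_s < duration_s)) {
    stop("need 0 < onset_s < offset_s < duration_s", call. = FALSE)
  }
  if (osc_freq_hz >= rate / 2) {
    stop("osc_freq_hz must be below Nyquist", call. = FALSE)
  }
  n <- round(rate * duration_s)
  t <- (seq_len(n) - 1) / rate

  # DC shift: sigmoid ramp starting slightly before onset, recovering
  # after offset with the slow-wave time constant
  ramp_s <- max(2, 0.05 * (offset_s - onset_s))
  up <- 1 / (1 + exp(-(t - (onset_s - ramp_s / 2)) / (ramp_s / 4)))
  down <- 1 / (1 + exp(-(t - offset_s) / (sd_wave_tau_s / 4)))
  dc <- dc_shift_amp * (up - down)

  # ictal oscillatory burst with a smooth Tukey-like envelope
  env <- rep(0, n)
  in_sz <- t >= onset_s & t < offset_s
  u <- (t[in_sz] - onset_s) / (offset_s - onset_s)
  env[in_sz] <- sin(pi * u)^2
  osc <- osc_amp * env * sin(2 * pi * osc_freq_hz * t)

  # post-ictal biphasic slow wave (difference of exponentials)
  sd_wave <- rep(0, n)
  post <- t >= offset_s
  tp <- t[post] - offset_s
  shape <- exp(-tp / sd_wave_tau_s) - exp(-tp / (sd_wave_tau_s / 4))
  peak <- 4^(-1 / 3) - 4^(-4 / 3)  # analytic max of the two-exponential shape
  sd_wave[post] <- sd_wave_amp * shape / peak

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  noise <- stats::rnorm(n, sd = noise_sd)

  mk <- function(x, lab) time_series(x, rate = rate, label = lab)
  list(
    signal = mk(dc + osc + sd_wave + noise, "surrogate_seizure"),
    components = list(
      dc_shift = mk(dc, "dc_shift"),
      oscillation = mk(osc, "oscillation"),
      sd_wave = mk(sd_wave, "sd_wave"),
      noise = mk(noise, "noise")
    )
  )
}
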