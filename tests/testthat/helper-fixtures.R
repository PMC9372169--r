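# Shared fixtures: the canonical simulated acquisition chain (one
# first-order 0.1 Hz high-pass stage, unity gain) and lazily cached
# UIR characterizations per sampling rate.

default_chain <- function() recording_chain()

.fixture_env <- new.env(parent = emptyenv())

# UIR characterized from a clean simulated step at the given rate
uir_fixture <- function(rate) {
  key <- paste0("uir_", rate)
  if (is.null(.fixture_env[[key]])) {
    rec <- simulate_recording(make_step(rate, 30, 5), default_chain())
    .fixture_env[[key]] <- characterize_uir(rec, "measured_step")
  }
  .fixture_env[[key]]
}

# the standard double-step test input (two 10 s pulses in 60 s)
double_step_fixture <- function(rate) {
  make_double_step(rate, 60, 10, 20, 35, 45, amplitude = 1)
}

# amplitude/phase at the spectrum bin nearest each frequency
amp_at <- function(sp, f) {
  sp$amplitude[vapply(f, function(x) which.min(abs(sp$freqs_hz - x)), 1L)]
}
phase_at <- function(sp, f) {
  sp$phase_rad[vapply(f, function(x) which.min(abs(sp$freqs_hz - x)), 1L)]
}

wrap_angle <- function(d) atan2(sin(d), cos(d))

# brute-force deconvolution oracle: solve the lower-triangular Toeplitz
# system conv(x, h) = y for the first n - m + 1 samples of x
toeplitz_deconv <- function(y, h) {
  n <- length(y)
  m <- length(h)
  k <- n - m + 1L
  T_ <- matrix(0, k, k)
  for (j in seq_len(k)) {
    rows <- j:min(k, j + m - 1L)
    T_[cbind(rows, j)] <- h[rows - j + 1L]
  }
  forwardsolve(T_, y[seq_len(k)])
}
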