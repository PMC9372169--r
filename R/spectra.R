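#' Single-sided amplitude (and phase) spectrum
#'
#' Computes a single-sided spectrum scaled so that a pure sine of
#' amplitude A at a bin-centred frequency yields a peak of height ~A.
#' By default the signal is mean-removed and Hann-windowed (with
#' coherent-gain amplitude correction) to limit leakage from finite
#' epochs, which matters at infraslow frequencies; `window = "none"`
#' gives the raw periodogram amplitudes (exact, and Parseval-consistent,
#' for bin-centred components).
#'
#' Phase convention: with the FFT kernel `exp(-2*pi*i*f*t)`,
#' `A*cos(2*pi*f*t)` has phase 0 and `A*sin(2*pi*f*t)` has phase
#' `-pi/2` at bin f.
#'
#' @param ts A [time_series()] of length >= 2.
#' @param window `"hann"` (default) or `"none"`.
#' @param remove_mean Subtract the mean before transforming (default
#'   `TRUE`).
#' @return An object of class `amp_spectrum`: list with `freqs_hz`
#'   (from 0 to Nyquist), `amplitude`, `phase_rad` in `(-pi, pi]`.
#' @export
amplitude_spectrum <- function(ts, window = c("hann", "none"),
                               remove_mean = TRUE) {
  stopifnot_time_series(ts)
  window <- match.arg(window)
  x <- ts$samples
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (remove_mean) x <- x - mean(x)
  w <- if (window == "hann") {
    0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)  # periodic Hann
  } else rep(1, n)
  X <- stats::fft(x * w)
  nb <- floor(n / 2) + 1L
  amp <- 2 * Mod(X[seq_len(nb)]) / sum(w)
  amp[1L] <- amp[1L] / 2
  if (n %% 2L == 0L) amp[nb] <- amp[nb] / 2
  structure(
    list(freqs_hz = (seq_len(nb) - 1) * ts$rate / n,
         amplitude = amp,
         phase_rad = Arg(X[seq_len(nb)])),
    class = "amp_spectrum"
  )
}

#' @export
print.amp_spectrum <- function(x, ...) {
  cat(sprintf("<amp_spectrum> %d bins, 0-%.4g Hz (df = %.4g Hz)\n",
              length(x$freqs_hz), max(x$freqs_hz), x$freqs_hz[2L]))
  pk <- order(x$amplitude, decreasing = TRUE)[seq_len(min(5, length(x$amplitude)))]
  cat("  top bins:",
      paste(sprintf("%.4g Hz (%.3g)", x$freqs_hz[pk], x$amplitude[pk]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Phase spectrum with an amplitude floor
#'
#' Same transform as [amplitude_spectrum()], but phases are reported
#' only at bins whose amplitude exceeds `floor_frac` of the maximum;
#' below-floor bins carry `NA` so that meaningless noise phases do not
#' enter comparisons.
#'
#' @inheritParams amplitude_spectrum
#' @param floor_frac Amplitude floor as a fraction of the spectrum
#'   maximum (default 0.01).
#' @return An `amp_spectrum` whose `phase_rad` is `NA` below the floor.
#' @export
phase_spectrum <- function(ts, window = c("hann", "none"),
                           floor_frac = 0.01) {
  sp <- amplitude_spectrum(ts, window = window)
  sp$phase_rad[sp$amplitude < floor_frac * max(sp$amplitude)] <- NA_real_
  sp
}

# phase at the bin nearest each target frequency
spectrum_phase_at <- function(sp, f_hz) {
  idx <- vapply(f_hz, function(f) which.min(abs(sp$freqs_hz - f)), 1L)
  sp$phase_rad[idx]
}

# amplitude at the bin nearest each target frequency
spectrum_amplitude_at <- function(sp, f_hz) {
  idx <- vapply(f_hz, function(f) which.min(abs(sp$freqs_hz - f)), 1L)
  sp$amplitude[idx]
}

#' Reconstruction fidelity report
#'
#' Quantifies how well a reconstruction restores a known input,
#' relative to the recorded (distorted) output: Pearson correlations of
#' the time series, the amplitude spectra, and the phase spectra of the
#' input against each of the two signals (six values).  Spectral
#' comparisons are restricted to `f_band` (half-open `[lo, hi)`).
#' Phase correlations use wrapped phases at the bins where the input
#' amplitude exceeds the phase floor: for sparse synthetic spectra the
#' phase sequence across disjoint component clusters contains jumps of
#' exactly pi, where unwrapping is ill-defined and would scramble two
#' nearly identical spectra into divergent sequences.
#'
#' @param input Ground-truth input [time_series()].
#' @param recorded Recorded output (same rate and length).
#' @param reconstruction Inverse-filtered reconstruction (same rate and
#'   length).
#' @param f_band Frequency band `c(lo, hi)` for the spectral
#'   correlations.
#' @param floor_frac Amplitude floor for phase bins (default 0.01).
#' @return An object of class `fidelity_report`: list with `recorded`
#'   and `reconstruction` (each `c(r_time, r_amplitude, r_phase)`) and
#'   `f_band`.
#' @export
fidelity_report <- function(input, recorded, reconstruction,
                            f_band = c(0, Inf), floor_frac = 0.01) {
  for (s in list(input, recorded, reconstruction)) stopifnot_time_series(s)
  if (length(input) != length(recorded) ||
      length(input) != length(reconstruction) ||
      !isTRUE(all.equal(input$rate, recorded$rate)) ||
      !isTRUE(all.equal(input$rate, reconstruction$rate))) {
    stop("all three signals must share rate and length", call. = FALSE)
  }
  if (stats::var(input$samples) == 0 ||
      stats::var(recorded$samples) == 0 ||
      stats::var(reconstruction$samples) == 0) {
    stop("correlation undefined for a zero-variance signal", call. = FALSE)
  }
  sp_in <- amplitude_spectrum(input)
  sp_rec <- amplitude_spectrum(recorded)
  sp_rc <- amplitude_spectrum(reconstruction)
  band <- sp_in$freqs_hz >= f_band[1L] & sp_in$freqs_hz < f_band[2L]
  ph_ok <- band & sp_in$amplitude >= floor_frac * max(sp_in$amplitude)

  one <- function(sig, sp) {
    c(r_time = stats::cor(input$samples, sig$samples),
      r_amplitude = stats::cor(sp_in$amplitude[band], sp$amplitude[band]),
      r_phase = stats::cor(sp_in$phase_rad[ph_ok], sp$phase_rad[ph_ok]))
  }
  structure(
    list(recorded = one(recorded, sp_rec),
         reconstruction = one(reconstruction, sp_rc),
         f_band = f_band),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> Pearson r of input vs:\n")
  m <- rbind(recorded = x$recorded, reconstruction = x$reconstruction)
  print(round(m, 4))
  cat(sprintf("  spectral band: [%g, %g) Hz\n", x$f_band[1L], x$f_band[2L]))
  invisible(x)
}

#' @export
as.data.frame.fidelity_report <- function(x, ...) {
  data.frame(comparison = c("recorded", "reconstruction"),
             r_time = c(x$recorded["r_time"], x$reconstruction["r_time"]),
             r_amplitude = c(x$recorded["r_amplitude"],
                             x$reconstruction["r_amplitude"]),
             r_phase = c(x$recorded["r_phase"],
                         x$reconstruction["r_phase"]),
             row.names = NULL)
}
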