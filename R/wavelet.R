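#' Morlet wavelet scalogram
#'
#' Time-frequency power via convolution with complex Morlet wavelets
#' (a complex sinusoid under a Gaussian envelope with a fixed number of
#' cycles per frequency, default 6).  Wavelets are normalized so that a
#' unit-amplitude sine yields power ~1 at its ridge.  Samples within
#' one wavelet half-length of either edge lie inside the cone of
#' influence and are flagged per frequency in `edge_samples`.
#'
#' @param ts A [time_series()].
#' @param freqs_hz Analysis frequencies, all below Nyquist; for
#'   infraslow work a logarithmic grid reaching below 0.01 Hz is
#'   typical (see [log_freq_grid()]).
#' @param cycles Number of wavelet cycles (default 6); more cycles
#'   sharpen frequency resolution at the cost of time resolution.
#' @return An object of class `scalogram`: `times_s`, `freqs_hz`,
#'   `power` (frequency x time matrix, `>= 0`), `edge_samples`
#'   (per-frequency half-length of the cone of influence, in samples).
#' @export
morlet_scalogram <- function(ts, freqs_hz, cycles = 6) {
  stopifnot_time_series(ts)
  if (any(freqs_hz <= 0) || any(freqs_hz >= ts$rate / 2)) {
    stop("analysis frequencies must lie in (0, Nyquist)", call. = FALSE)
  }
  x <- ts$samples - mean(ts$samples)
  n <- length(x)
  power <- matrix(0, nrow = length(freqs_hz), ncol = n)
  edge <- integer(length(freqs_hz))
  for (i in seq_along(freqs_hz)) {
    f <- freqs_hz[i]
    sigma_t <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma_t * ts$rate)
    tt <- (-half:half) / ts$rate
    env <- exp(-tt^2 / (2 * sigma_t^2))
    psi <- env * exp(2i * pi * f * tt)
    psi <- psi / sum(env)             # unit response to exp(2*pi*i*f*t)
    w <- .fft_convolve_same(x, psi)
    power[i, ] <- Mod(2 * w)^2        # x2: real sine -> analytic amplitude
    edge[i] <- min(half, n)
  }
  structure(
    list(times_s = ts_times(ts), freqs_hz = freqs_hz, power = power,
         edge_samples = edge, cycles = cycles, rate = ts$rate),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "<scalogram> %d freqs (%.4g-%.4g Hz) x %d times, %g cycles\n",
    length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
    length(x$times_s), x$cycles))
  invisible(x)
}

#' Logarithmic frequency grid
#'
#' @param f_lo,f_hi Band edges in Hz.
#' @param n Number of frequencies.
#' @return Log-spaced frequencies from `f_lo` to `f_hi`.
#' @export
log_freq_grid <- function(f_lo, f_hi, n = 16) {
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

#' Interior (cone-free) time mask of a scalogram
#'
#' @param sg A [morlet_scalogram()] result.
#' @return Logical vector over time samples that lie outside the cone
#'   of influence at every analysis frequency.
#' @export
scalogram_interior <- function(sg) {
  n <- length(sg$times_s)
  half <- max(sg$edge_samples)
  ok <- rep(TRUE, n)
  if (half >= 1L) {
    ok[seq_len(min(half, n))] <- FALSE
    ok[seq.int(max(1L, n - half + 1L), n)] <- FALSE
  }
  ok
}

#' Band-integrated wavelet power over time
#'
#' Scalogram power integrated (trapezoid over frequency) across
#' `[f_lo, f_hi)` per time sample; the default band is the sub-0.1 Hz
#' infraslow band.
#'
#' @param ts A [time_series()].
#' @param f_lo,f_hi Band edges, `f_lo < f_hi <= Nyquist`.
#' @param freqs_hz Analysis grid; defaults to a log grid of 12
#'   frequencies spanning the band (the lower edge is floored at
#'   3 / duration so at least three periods fit the epoch).
#' @param cycles Morlet cycles (default 6).
#' @return A `time_series` of band power (arbitrary units squared),
#'   with the scalogram's cone-of-influence mask in attribute
#'   `interior`.
#' @export
band_power_timecourse <- function(ts, f_lo = 0, f_hi = 0.1,
                                  freqs_hz = NULL, cycles = 6) {
  stopifnot_time_series(ts)
  if (!(f_lo < f_hi) || f_hi > ts$rate / 2) {
    stop("need f_lo < f_hi <= Nyquist", call. = FALSE)
  }
  if (is.null(freqs_hz)) {
    lo_eff <- max(f_lo, 3 / ts_duration(ts))
    if (lo_eff >= f_hi) {
      stop("epoch too short to resolve the requested band", call. = FALSE)
    }
    freqs_hz <- log_freq_grid(lo_eff, f_hi * 0.999, n = 12)
  }
  sg <- morlet_scalogram(ts, freqs_hz, cycles = cycles)
  sel <- sg$freqs_hz >= f_lo & sg$freqs_hz < f_hi
  p <- sg$power[sel, , drop = FALSE]
  f <- sg$freqs_hz[sel]
  bp <- if (length(f) > 1L) {
    df <- diff(f)
    as.numeric(crossprod((p[-1L, , drop = FALSE] +
                            p[-length(f), , drop = FALSE]) / 2, df))
  } else p[1L, ]
  out <- time_series(pmax(bp, 0), rate = ts$rate,
                     label = paste0(ts$label, "_bandpower"), t0 = ts$t0)
  attr(out, "interior") <- scalogram_interior(sg)
  out
}

# linear convolution via FFT, trimmed to "same" alignment with x
.fft_convolve_same <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m - 1L, 2)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  K <- stats::fft(c(k, rep(0, nfft - m)))
  full <- stats::fft(X * K, inverse = TRUE) / nfft
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}
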