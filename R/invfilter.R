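#' Inverse-filter configuration
#'
#' Bundles the drift-correction and length-guard parameters of the
#' inverse filter.  Deconvolution can introduce a slow triangular drift
#' (accumulated rounding error) whose fundamental frequency is
#' `1 / (2 * epoch length)`; reconstructions are therefore high-pass
#' filtered at `drift_cutoff_hz`, and epochs must span at least
#' `min_periods` periods of the lowest frequency of interest so the
#' drift cannot masquerade as signal.
#'
#' @param drift_cutoff_hz Drift-filter cutoff in Hz (default 0.005).
#' @param drift_order Butterworth order of the drift filter (default 2).
#' @param drift_zero_phase Apply the drift filter forward-backward
#'   (default `TRUE`); a causal filter would reintroduce the phase
#'   distortion the inverse filter removes.
#' @param min_periods Minimum number of periods of `f_low_hz` an epoch
#'   must span (default 3).
#' @param f_low_hz Lowest frequency of interest (default =
#'   `drift_cutoff_hz`).
#' @param chunk_len_s,chunk_overlap_s Optional chunking parameters for
#'   [chunked_inverse_filter()].
#' @return An object of class `inverse_filter_config`.
#' @export
inverse_filter_config <- function(drift_cutoff_hz = 0.005,
                                  drift_order = 2L,
                                  drift_zero_phase = TRUE,
                                  min_periods = 3L,
                                  f_low_hz = drift_cutoff_hz,
                                  chunk_len_s = NULL,
                                  chunk_overlap_s = NULL) {
  if (drift_cutoff_hz <= 0) stop("drift_cutoff_hz must be > 0", call. = FALSE)
  if (min_periods < 1L) stop("min_periods must be >= 1", call. = FALSE)
  if (!is.null(chunk_len_s) && !is.null(chunk_overlap_s) &&
      chunk_overlap_s >= chunk_len_s) {
    stop("chunk overlap must be smaller than the chunk length",
         call. = FALSE)
  }
  structure(
    list(drift_cutoff_hz = drift_cutoff_hz,
         drift_order = as.integer(drift_order),
         drift_zero_phase = isTRUE(drift_zero_phase),
         min_periods = as.integer(min_periods),
         f_low_hz = f_low_hz,
         chunk_len_s = chunk_len_s, chunk_overlap_s = chunk_overlap_s),
    class = "inverse_filter_config"
  )
}

#' Fundamental frequency of the deconvolution drift
#'
#' The triangular drift sometimes introduced by deconvolution has
#' frequency `1 / (2 * epoch length)`.
#'
#' @param epoch_length_s Epoch length in seconds, `> 0`.
#' @return Drift frequency in Hz.
#' @export
drift_frequency <- function(epoch_length_s) {
  if (any(epoch_length_s <= 0)) {
    stop("epoch length must be positive", call. = FALSE)
  }
  1 / (2 * epoch_length_s)
}

#' Minimum epoch length for a lowest frequency of interest
#'
#' Epochs must span at least `min_periods` periods (default 3) of the
#' lowest frequency of interest; e.g. 600 s to study 0.005 Hz.
#'
#' @param f_low_hz Lowest frequency of interest in Hz, `> 0`.
#' @param min_periods Required number of periods (default 3).
#' @return Minimum epoch length in seconds.
#' @export
min_length_for <- function(f_low_hz, min_periods = 3L) {
  if (any(f_low_hz <= 0)) {
    stop("f_low_hz must be positive", call. = FALSE)
  }
  min_periods / f_low_hz
}

# long-division quotient via recursive inverse filtering:
# x[n] = (y[n] - sum_{k>=2} h[k] x[n-k+1]) / h[1], full length of y
.deconv_raw <- function(y, h) {
  if (length(h) == 1L) return(y / h[1L])
  as.numeric(stats::filter(y / h[1L], -h[-1L] / h[1L],
                           method = "recursive"))
}

#' Deconvolve a recording by a unit impulse response
#'
#' Time-domain long division (equivalently, recursive inverse filtering
#' by `h`): returns `x` such that `conv(x, h)` reproduces `y` over the
#' valid region.  The quotient has `length(y) - length(h) + 1` samples;
#' it is re-padded to the input length by holding the last quotient
#' value so downstream sample-time alignment is preserved (the padded
#' region is reported in the `n_valid` attribute).  The result is
#' scaled by the UIR's normalization constant.
#'
#' @param y Recorded [time_series()], zero-meaned by convention (see
#'   [zero_mean()]; [inverse_filter()] does this for you).
#' @param uir A `uir_model`; if its rate differs from `y$rate` it is
#'   re-derived at `y`'s rate via [uir_at_rate()].
#' @return A `time_series` reconstruction with attribute `n_valid`.
#' @export
deconvolve <- function(y, uir) {
  stopifnot_time_series(y)
  if (!inherits(uir, "uir_model")) stop("need a uir_model", call. = FALSE)
  if (!isTRUE(all.equal(uir$rate, y$rate))) {
    uir <- uir_at_rate(uir, y$rate)
  }
  h <- uir$h
  if (abs(h[1L]) < 1e-12 * max(abs(h), 1e-300)) {
    stop("unstable UIR: h[1] is (near) zero, long division undefined",
         call. = FALSE)
  }
  n <- length(y$samples)
  m <- length(h)
  if (m > n) stop("UIR longer than the signal", call. = FALSE)
  q <- .deconv_raw(y$samples, h) * uir$norm
  n_valid <- n - m + 1L
  x <- c(q[seq_len(n_valid)], rep(q[n_valid], m - 1L))
  out <- time_series(x, rate = y$rate,
                     label = paste0(y$label, "_deconv"), t0 = y$t0)
  attr(out, "n_valid") <- n_valid
  out
}

#' Remove the deconvolution drift with a high-pass filter
#'
#' Applies the configured Butterworth high-pass (default order 2,
#' 0.005 Hz), zero-phase by default so the phase restoration achieved
#' by deconvolution is not re-broken.
#'
#' @param ts A [time_series()].
#' @param config An [inverse_filter_config()].
#' @return Filtered `time_series`.  If the epoch is shorter than the
#'   filter warm-up (3 periods of the cutoff) a warning is issued and
#'   the output carries attribute `short_epoch = TRUE`.
#' @export
remove_drift <- function(ts, config = inverse_filter_config()) {
  stopifnot_time_series(ts)
  if (ts$rate <= 2 * config$drift_cutoff_hz) {
    stop("sampling rate must exceed twice the drift cutoff", call. = FALSE)
  }
  short <- ts_duration(ts) < 3 / config$drift_cutoff_hz
  if (short) {
    warning(sprintf(
      "epoch (%.3g s) is shorter than 3 periods of the %g Hz drift cutoff",
      ts_duration(ts), config$drift_cutoff_hz))
  }
  spec <- filter_spec("butterworth_highpass", order = config$drift_order,
                      cutoff_hz = config$drift_cutoff_hz,
                      zero_phase = config$drift_zero_phase)
  out <- apply_filter(ts, spec)
  if (short) attr(out, "short_epoch") <- TRUE
  out
}

#' The deconvolution-based inverse filter
#'
#' Full reconstruction pipeline: mean-zeroing, deconvolution by the
#' system's UIR, and drift removal.  The epoch must be at least
#' [min_length_for()] `(f_low_hz, min_periods)` seconds long (override
#' with `force = TRUE`), so that the deconvolution drift at
#' `1 / (2 * epoch)` Hz stays well below the band of interest.
#'
#' @param y Recorded [time_series()].
#' @param uir A `uir_model` from [characterize_uir()] or [read_uir()].
#' @param config An [inverse_filter_config()].
#' @param force Skip the minimum-length guard.
#' @param verbose Emit a log message with UIR provenance, epoch length
#'   and predicted drift frequency.
#' @return Reconstructed `time_series`; attribute `log` carries the run
#'   record, `n_valid` the unpadded deconvolution length.
#' @export
inverse_filter <- function(y, uir, config = inverse_filter_config(),
                           force = FALSE, verbose = FALSE) {
  stopifnot_time_series(y)
  need_s <- min_length_for(config$f_low_hz, config$min_periods)
  if (!force && ts_duration(y) < need_s) {
    stop(sprintf(
      "epoch too short: %.6g s, but %.6g s required for f_low = %g Hz (%d periods); use force = TRUE to override",
      ts_duration(y), need_s, config$f_low_hz, config$min_periods),
      call. = FALSE)
  }
  x <- deconvolve(zero_mean(y), uir)
  n_valid <- attr(x, "n_valid")
  out <- remove_drift(x, config)
  log <- list(
    uir_source = uir$source, uir_taps = length(uir$h),
    epoch_length_s = ts_duration(y),
    predicted_drift_hz = drift_frequency(ts_duration(y)),
    drift_cutoff_hz = config$drift_cutoff_hz,
    forced = isTRUE(force) && ts_duration(y) < need_s
  )
  if (verbose) {
    message(sprintf(
      "inverse_filter: UIR %s (%d taps), epoch %.6g s, predicted drift %.3g Hz, drift cutoff %g Hz",
      log$uir_source, log$uir_taps, log$epoch_length_s,
      log$predicted_drift_hz, log$drift_cutoff_hz))
  }
  attr(out, "n_valid") <- n_valid
  attr(out, "log") <- log
  out
}

#' Inverse filter a long recording in overlapping chunks
#'
#' Long epochs can be reconstructed as a series of shorter overlapping
#' clips that are inverse filtered independently, cross-faded over the
#' overlap and concatenated.  Each chunk must satisfy the minimum-length
#' rule, and the overlap must span at least three UIR durations so the
#' deconvolution edge regions never reach the blended output.
#'
#' @param y Recorded [time_series()].
#' @param uir A `uir_model`.
#' @param config An [inverse_filter_config()] with `chunk_len_s` and
#'   `chunk_overlap_s` set.
#' @param verbose Emit per-chunk log messages.
#' @return Reconstructed `time_series` of the same length as `y`.
#' @export
chunked_inverse_filter <- function(y, uir, config, verbose = FALSE) {
  stopifnot_time_series(y)
  if (is.null(config$chunk_len_s) || is.null(config$chunk_overlap_s)) {
    stop("config must set chunk_len_s and chunk_overlap_s", call. = FALSE)
  }
  rate <- y$rate
  uir_y <- if (isTRUE(all.equal(uir$rate, rate))) uir else
    uir_at_rate(uir, rate)
  uir_dur <- length(uir_y$h) / rate
  if (config$chunk_overlap_s < 3 * uir_dur) {
    stop(sprintf(
      "chunk overlap %.3g s is too small: need >= 3 UIR durations (%.3g s)",
      config$chunk_overlap_s, 3 * uir_dur), call. = FALSE)
  }
  if (config$chunk_len_s < min_length_for(config$f_low_hz,
                                          config$min_periods)) {
    stop("chunk_len_s violates the minimum-length rule", call. = FALSE)
  }
  n <- length(y$samples)
  len <- round(config$chunk_len_s * rate)
  ov <- round(config$chunk_overlap_s * rate)
  if (len >= n) {
    return(inverse_filter(y, uir_y, config, verbose = verbose))
  }
  step <- len - ov
  starts <- seq(1L, n - len + 1L, by = step)
  if (starts[length(starts)] + len - 1L < n) {
    starts <- c(starts, n - len + 1L)  # final chunk flush with the end
  }
  acc <- numeric(n)
  wsum <- numeric(n)
  for (s0 in starts) {
    idx <- s0:(s0 + len - 1L)
    chunk <- time_series(y$samples[idx], rate = rate, label = y$label,
                         t0 = y$t0 + (s0 - 1L) / rate)
    rec <- inverse_filter(chunk, uir_y, config, verbose = verbose)
    w <- rep(1, len)
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(ov) / (ov + 1))  # raised cosine
    if (s0 > 1L) w[seq_len(ov)] <- ramp
    if (s0 + len - 1L < n) w[(len - ov + 1L):len] <- rev(ramp)
    acc[idx] <- acc[idx] + rec$samples * w
    wsum[idx] <- wsum[idx] + w
  }
  time_series(acc / wsum, rate = rate,
              label = paste0(y$label, "_deconv"), t0 = y$t0)
}
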