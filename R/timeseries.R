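#' Uniformly sampled time series
#'
#' The basic container used throughout the package: a real-valued signal
#' sampled at a constant rate, in arbitrary units.  Sample `i` (1-based)
#' sits at time `t0 + (i - 1) / rate` seconds; epochs are half-open
#' `[start, end)` intervals.
#'
#' @param samples Numeric vector of finite sample values (arbitrary units).
#' @param rate Sampling frequency in samples/s, `> 0`.
#' @param label Free-text channel name.
#' @param t0 Start time in seconds of the first sample.
#'
#' @return An object of class `time_series`: a list with elements
#'   `samples`, `rate`, `label`, `t0`.
#' @examples
#' ts <- time_series(sin(2 * pi * 0.05 * (0:999) / 10), rate = 10)
#' ts_duration(ts)
#' @export
time_series <- function(samples, rate, label = "signal", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("time_series needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("time_series samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("sampling rate must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         label = as.character(label)[1L], t0 = as.numeric(t0)[1L]),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series> %s: %d samples @ %g samples/s (%.6g s), t0 = %g s\n",
    x$label, length(x$samples), x$rate, ts_duration(x), x$t0
  ))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$samples), max(x$samples), mean(x$samples)))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time_s = ts_times(x), value = x$samples)
}

#' Duration of a time series in seconds
#'
#' Defined as `length / rate`, i.e. the half-open support of the signal.
#' @param ts A [time_series()].
#' @return Duration in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' Sample times of a time series
#'
#' @param ts A [time_series()].
#' @return Numeric vector of times in seconds, `t0 + (0:(n-1)) / rate`.
#' @export
ts_times <- function(ts) ts$t0 + (seq_along(ts$samples) - 1) / ts$rate

stopifnot_time_series <- function(ts) {
  if (!inherits(ts, "time_series")) {
    stop("expected a time_series object", call. = FALSE)
  }
  invisible(ts)
}

#' Subtract the mean of a signal
#'
#' Signals are zeroed by mean subtraction before deconvolution so the
#' long-division recursion does not have to track a DC offset.  Idempotent.
#'
#' @param ts A [time_series()].
#' @return A `time_series` with zero mean, same rate and length.
#' @export
zero_mean <- function(ts) {
  stopifnot_time_series(ts)
  ts$samples <- ts$samples - mean(ts$samples)
  ts
}

#' Downsample a time series with anti-alias filtering
#'
#' Zero-phase anti-alias low-pass (8th-order Butterworth at 0.45 times
#' the target rate) followed by cubic-spline evaluation on the new time
#' grid; large ratios are decimated in stages of at most 10x so the
#' digital filter stays well conditioned.  Integer-ratio decimation
#' falls on original sample instants, so sub-Nyquist content is
#' preserved without interpolation error.  Infraslow work does not need
#' high sampling rates, and decimation keeps deconvolution cheap.
#'
#' @param ts A [time_series()].
#' @param target_rate New rate in samples/s, `<= ts$rate`.
#' @return A `time_series` at `target_rate`.
#' @export
downsample <- function(ts, target_rate) {
  stopifnot_time_series(ts)
  if (target_rate > ts$rate) {
    stop("upsampling not supported: target_rate ", target_rate,
         " > rate ", ts$rate, call. = FALSE)
  }
  if (isTRUE(all.equal(target_rate, ts$rate))) {
    return(ts)
  }
  while (ts$rate / target_rate > 10) {
    ts <- .downsample_once(ts, ts$rate / 10)
  }
  .downsample_once(ts, target_rate)
}

.downsample_once <- function(ts, target_rate) {
  fc <- 0.45 * target_rate
  bt <- signal::butter(8, fc / (ts$rate / 2), type = "low")
  filtered <- .filtfilt_odd(as.numeric(bt$b), as.numeric(bt$a),
                            ts$samples, ts$rate, fc)
  n_out <- floor(length(ts$samples) * target_rate / ts$rate)
  t_new <- ts$t0 + (seq_len(n_out) - 1) / target_rate
  out <- stats::spline(ts_times(ts), filtered, xout = t_new,
                       method = "fmm")$y
  time_series(out, rate = target_rate, label = ts$label, t0 = ts$t0)
}
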