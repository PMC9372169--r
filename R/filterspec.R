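#' Parametric description of a one-sided frequency-selective filter
#'
#' Describes the filters that appear in the recording chain (the AC
#' amplifier's high-pass input stage) and in drift correction.  A
#' `first_order_rc_highpass` is the single-pole RC coupling stage of an
#' AC amplifier; it is realized digitally as an order-1 Butterworth
#' high-pass, whose magnitude response equals the analog RC magnitude
#' `f / sqrt(f^2 + fc^2)`.
#'
#' @param kind One of `"butterworth_highpass"`, `"first_order_rc_highpass"`,
#'   `"allpass"`.
#' @param order Positive integer filter order (forced to 1 for the RC kind,
#'   ignored for allpass).
#' @param cutoff_hz Cutoff (half-power) frequency in Hz; ignored for allpass.
#' @param zero_phase If `TRUE` the filter is applied forward-backward
#'   ([signal::filtfilt()]); hardware stages are causal (`FALSE`).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("butterworth_highpass",
                                 "first_order_rc_highpass",
                                 "allpass"),
                        order = 1L, cutoff_hz = 0.1, zero_phase = FALSE) {
  kind <- match.arg(kind)
  if (kind == "first_order_rc_highpass") order <- 1L
  if (kind != "allpass") {
    if (order < 1L) stop("filter order must be >= 1", call. = FALSE)
    if (!is.finite(cutoff_hz) || cutoff_hz <= 0) {
      stop("cutoff_hz must be positive", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, order = as.integer(order),
         cutoff_hz = as.numeric(cutoff_hz),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$kind == "allpass") {
    cat("<filter_spec> allpass\n")
  } else {
    cat(sprintf("<filter_spec> %s, order %d, cutoff %g Hz, %s\n",
                x$kind, x$order, x$cutoff_hz,
                if (x$zero_phase) "zero-phase" else "causal"))
  }
  invisible(x)
}

# digital coefficients of a filter_spec at a given sampling rate
.filter_coefs <- function(spec, rate) {
  if (spec$kind == "allpass") {
    return(list(b = 1, a = 1))
  }
  if (spec$cutoff_hz >= rate / 2) {
    stop("filter cutoff ", spec$cutoff_hz,
         " Hz is at or above the Nyquist frequency ", rate / 2, " Hz",
         call. = FALSE)
  }
  bt <- signal::butter(spec$order, spec$cutoff_hz / (rate / 2), type = "high")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Apply a filter_spec to a time series
#'
#' Causal filters are initialized at steady state for the signal's first
#' sample (the pre-signal baseline), so no artificial startup transient
#' is introduced: a recording that begins on a settled baseline stays
#' settled.  Zero-phase filters use forward-backward filtering.
#'
#' @param ts A [time_series()].
#' @param spec A [filter_spec()].
#' @return Filtered `time_series`, same rate and length.
#' @export
apply_filter <- function(ts, spec) {
  stopifnot_time_series(ts)
  if (spec$kind == "allpass") return(ts)
  co <- .filter_coefs(spec, ts$rate)
  x <- ts$samples
  if (spec$zero_phase) {
    y <- .filtfilt_odd(co$b, co$a, x, ts$rate, spec$cutoff_hz)
  } else {
    # steady state for constant input x[1]: every past input = x[1],
    # every past output = x[1] * H(z = 1)
    x0 <- x[1L]
    y0 <- x0 * sum(co$b) / sum(co$a)
    nfilt <- length(co$a)
    y <- .causal_filter(co$b, co$a, x, x0, y0, nfilt)
  }
  time_series(as.numeric(y), rate = ts$rate, label = ts$label, t0 = ts$t0)
}

# forward-backward filtering with odd-reflection edge padding; the pad
# spans several filter time constants so low-cutoff high-pass filters do
# not leave startup transients inside the signal
.filtfilt_odd <- function(b, a, x, rate, cutoff_hz) {
  n <- length(x)
  tau_s <- 1 / (2 * pi * max(cutoff_hz, .Machine$double.eps))
  padlen <- min(n - 1L, as.integer(ceiling(3 * tau_s * rate)) + 3L *
                  max(length(a), length(b)))
  if (padlen < 1L) padlen <- min(n - 1L, 3L * max(length(a), length(b)))
  pre  <- 2 * x[1L] - x[(padlen + 1L):2L]
  post <- 2 * x[n]  - x[(n - 1L):(n - padlen)]
  xe <- c(pre, x, post)
  y <- .causal_filter(b, a, xe, xe[1L], xe[1L] * sum(b) / sum(a), length(a))
  y <- rev(.causal_filter(b, a, rev(y), y[length(y)],
                          y[length(y)] * sum(b) / sum(a), length(a)))
  y[(padlen + 1L):(padlen + n)]
}

# direct-form IIR with explicit initial input/output history
.causal_filter <- function(b, a, x, x0, y0, nfilt) {
  npad <- nfilt - 1L
  if (npad == 0L) {
    return(stats::filter(x * b[1L] / a[1L], numeric(0),
                         method = "recursive"))
  }
  xp <- c(rep(x0, npad), x)
  # FIR (numerator) part
  v <- stats::filter(xp, b / a[1L], method = "convolution", sides = 1)
  v <- as.numeric(v)[(npad + 1L):length(xp)]
  # IIR (denominator) part with seeded output history
  ar <- -a[-1L] / a[1L]
  y <- stats::filter(v, ar, method = "recursive", init = rep(y0, npad))
  as.numeric(y)
}
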