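#' Simulated AC-coupled recording chain
#'
#' Models the acquisition system as an ordered list of causal filters
#' (the amplifier's high-pass coupling stage and any others), a gain,
#' optional hard clipping (amplifier saturation), and optional additive
#' Gaussian noise.  With no clipping and no noise the chain is a linear
#' time-invariant system, so its output is the convolution of the input
#' with the chain's unit impulse response — exactly the situation the
#' inverse filter is designed to undo.
#'
#' @param filters List of [filter_spec()] objects, applied in order and
#'   causally (`zero_phase` is forced off: hardware is causal).
#' @param gain Scalar gain.
#' @param clip_range Optional `c(lo, hi)` saturation bounds.
#' @param noise Optional [noise_spec()] for measurement noise.
#' @return An object of class `recording_chain`.
#' @export
recording_chain <- function(filters = list(
                              filter_spec("first_order_rc_highpass",
                                          cutoff_hz = 0.1)),
                            gain = 1, clip_range = NULL, noise = NULL) {
  if (inherits(filters, "filter_spec")) filters <- list(filters)
  stopifnot(all(vapply(filters, inherits, logical(1), "filter_spec")))
  filters <- lapply(filters, function(f) { f$zero_phase <- FALSE; f })
  if (!is.null(clip_range)) {
    if (length(clip_range) != 2L || clip_range[1L] >= clip_range[2L]) {
      stop("clip_range must be c(lo, hi) with lo < hi", call. = FALSE)
    }
  }
  if (!is.null(noise) && !inherits(noise, "noise_spec")) {
    stop("noise must be a noise_spec or NULL", call. = FALSE)
  }
  structure(list(filters = filters, gain = as.numeric(gain),
                 clip_range = clip_range, noise = noise),
            class = "recording_chain")
}

#' @export
print.recording_chain <- function(x, ...) {
  cat(sprintf("<recording_chain> %d filter(s), gain %g%s%s\n",
              length(x$filters), x$gain,
              if (is.null(x$clip_range)) "" else
                sprintf(", clip [%g, %g]", x$clip_range[1], x$clip_range[2]),
              if (is.null(x$noise)) "" else
                sprintf(", noise SNR %g", x$noise$snr_linear)))
  for (f in x$filters) print(f)
  invisible(x)
}

#' Pass a signal through a simulated recording chain
#'
#' Produces what the acquisition system would have recorded for a known
#' input: `clip(gain * filters(x)) + noise`, same rate and length as the
#' input.  Filter state is initialized to steady state for the input's
#' first sample, so signals that start on a settled baseline have no
#' artificial startup transient.
#'
#' @param ts Input [time_series()].
#' @param chain A [recording_chain()].
#' @return The simulated recorded output as a `time_series`.
#' @export
simulate_recording <- function(ts, chain) {
  stopifnot_time_series(ts)
  if (!inherits(chain, "recording_chain")) {
    stop("need a recording_chain", call. = FALSE)
  }
  out <- ts
  for (f in chain$filters) out <- apply_filter(out, f)
  out$samples <- out$samples * chain$gain
  if (!is.null(chain$clip_range)) {
    out$samples <- pmin(pmax(out$samples, chain$clip_range[1L]),
                        chain$clip_range[2L])
  }
  if (!is.null(chain$noise)) out <- add_noise(out, chain$noise)
  out$label <- paste0(ts$label, "_recorded")
  out
}

#' Closed-form magnitude response of a filter_spec
#'
#' The analytic attenuation ratio `|H(f)|` used as an oracle for the
#' digital filters: for an order-n Butterworth high-pass
#' `1 / sqrt(1 + (fc/f)^(2n))`; the first-order RC stage is the n = 1
#' case.  Allpass returns 1.
#'
#' @param spec A [filter_spec()].
#' @param f_hz Frequency (vectorized), `>= 0`.
#' @return Attenuation ratio(s) in `[0, 1]`; 0 at f = 0 for high-pass.
#' @export
analytic_attenuation <- function(spec, f_hz) {
  if (any(f_hz < 0)) stop("f_hz must be >= 0", call. = FALSE)
  if (spec$kind == "allpass") return(rep(1, length(f_hz)))
  n <- if (spec$kind == "first_order_rc_highpass") 1L else spec$order
  ifelse(f_hz == 0, 0,
         1 / sqrt(1 + (spec$cutoff_hz / f_hz)^(2 * n)))
}

#' Closed-form phase response of a causal high-pass filter_spec
#'
#' For the first-order RC high-pass the phase lead is `atan(fc / f)`;
#' used as an oracle for phase-distortion tests.  Only defined here for
#' first-order kinds; allpass returns 0.
#'
#' @param spec A [filter_spec()].
#' @param f_hz Frequency (vectorized), `> 0`.
#' @return Phase in radians.
#' @export
analytic_phase_lead <- function(spec, f_hz) {
  if (spec$kind == "allpass") return(rep(0, length(f_hz)))
  if (spec$kind == "butterworth_highpass" && spec$order != 1L) {
    stop("closed-form phase implemented for first-order filters only",
         call. = FALSE)
  }
  atan(spec$cutoff_hz / f_hz)
}
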