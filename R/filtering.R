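## Zero-phase Butterworth low-pass filtering.
##
## Smoothing runs on the four quaternion components independently (after
## antipodal sign alignment), followed by renormalization — the standard
## treatment when orientation streams, rather than derived angles, are
## filtered.  The filter is applied forward and backward, so the effective
## attenuation order is twice the design order and the phase response is zero;
## a 4th-order design therefore behaves as an 8th-order magnitude response.
##
## Edge handling: the series is extended by odd reflection about its
## endpoints and each pass starts from the filter's steady state for the
## first extended sample.  A constant series is therefore reproduced to
## machine precision (unit DC gain).

butter_lowpass <- function(cutoff, order, sample_rate) {
  if (!is.finite(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  if (!is.finite(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  if (cutoff >= sample_rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         sample_rate / 2, " Hz)")
  }
  if (order < 1) stop("filter order must be >= 1")
  bf <- signal::butter(order, 2 * cutoff / sample_rate, type = "low")
  list(b = as.numeric(bf$b), a = as.numeric(bf$a))
}

## One causal IIR pass started from steady state for a level equal to the
## first sample, so constants pass through exactly.
iir_steady <- function(b, a, x) {
  dc <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1L], length(b) - 1L),
                            init.y = rep(x[1L] * dc, length(a) - 1L)))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward 4th-order (by default) Butterworth smoothing with odd
#' edge reflection and steady-state initialization.  Zero phase lag; the
#' two passes double the effective attenuation order.  A constant input is
#' returned unchanged (DC gain 1) and the output has the same length as the
#' input.
#'
#' @param x Numeric series (one channel).
#' @param cutoff Cutoff frequency in Hz (default 6).
#' @param order Design order of the Butterworth filter (default 4); the
#'   forward-backward application doubles the effective order.
#' @param sample_rate Sampling frequency in Hz (default 96).
#' @return Filtered series, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 96)
#' y <- sin(2 * pi * 1 * t) + 0.2 * sin(2 * pi * 40 * t)
#' smooth <- lowpass_filter(y)          # 40 Hz component removed
lowpass_filter <- function(x, cutoff = 6, order = 4, sample_rate = 96) {
  if (!is.numeric(x)) stop("series must be numeric")
  if (anyNA(x) || !all(is.finite(x))) stop("series must be finite")
  n <- length(x)
  if (n < 3 * order) {
    stop("series too short for filtering: need at least ", 3 * order,
         " samples, got ", n)
  }
  coefs <- butter_lowpass(cutoff, order, sample_rate)
  b <- coefs$b; a <- coefs$a
  pad <- min(3L * (max(length(a), length(b)) - 1L), n - 1L)
  front <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(front, x, back)
  y <- iir_steady(b, a, xp)
  y <- rev(iir_steady(b, a, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Low-pass filter a quaternion orientation stream
#'
#' Sign-aligns consecutive frames (see [sign_align()]), filters each of the
#' four components with [lowpass_filter()], and renormalizes every frame to
#' unit length.
#'
#' @param qmat n x 4 quaternion frame matrix.
#' @inheritParams lowpass_filter
#' @return Filtered unit-norm n x 4 matrix.
#' @export
filter_orientation <- function(qmat, cutoff = 6, order = 4, sample_rate = 96) {
  m <- sign_align(as_quat_matrix(qmat))
  out <- apply(m, 2L, lowpass_filter, cutoff = cutoff, order = order,
               sample_rate = sample_rate)
  quat_normalize(matrix(out, ncol = 4L,
                        dimnames = list(NULL, c("w", "x", "y", "z"))))
}
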