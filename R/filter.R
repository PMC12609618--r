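#' Low-pass Butterworth design (digital, bilinear transform)
#'
#' Designs an order-`n` digital Butterworth low-pass filter with the cutoff
#' prewarped so the -3 dB point lands exactly at `cutoff`. Returns transfer
#' function coefficients `b` (numerator) and `a` (denominator), `a[1] = 1`.
#'
#' @param cutoff cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 2).
#' @return List with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_lowpass <- function(cutoff, fs, order = 2L) {
  if (cutoff <= 0 || cutoff >= fs / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency fs/2",
         call. = FALSE)
  }
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  # analog prototype poles on the unit circle, scaled to the prewarped cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p <- warped * exp(1i * theta)
  # bilinear transform of poles; all zeros map to z = -1
  pz <- (2 * fs + p) / (2 * fs - p)
  a <- Re(poly_from_roots(pz))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b) # unit DC gain
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (rt in r) cf <- c(cf, 0) - c(0, cf * rt)
  cf
}

#' Analytic magnitude response of the designed filter
#'
#' Exact gain of the digital Butterworth low-pass at frequency `f`, including
#' the bilinear frequency warping; `passes = 2` gives the squared (zero-phase
#' forward-backward) gain. For `f` well below Nyquist this approaches the
#' analog form `(1 + (f/cutoff)^(2*order))^(-passes/2)`.
#'
#' @inheritParams butter_lowpass
#' @param f frequency in Hz at which to evaluate the gain.
#' @param passes number of filter passes (2 for zero-phase filtering).
#' @return Gain (dimensionless, 1 at DC).
#' @export
butter_gain <- function(f, cutoff, fs, order = 2L, passes = 2L) {
  nu <- tan(pi * f / fs) / tan(pi * cutoff / fs)
  (1 + nu^(2 * order))^(-passes / 2)
}

# direct form II transposed IIR filter with initial state zi * x[1]
iir_filter <- function(b, a, x, scale_zi = x[1]) {
  n <- length(a) - 1L
  z <- lfilter_zi(b, a) * scale_zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1L) {
      for (j in seq_len(n - 1L)) {
        z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
      }
    }
    z[n] <- b[n + 1L] * xi - a[n + 1L] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial filter state for a unit step input, so that filtering a
# constant produces that constant with no start-up transient
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  A[, 1L] <- A[, 1L] - a[-1L]
  B <- b[-1L] - a[-1L] * b[1L]
  solve(diag(n) - A, B)
}

#' Zero-phase forward-backward filtering of a numeric vector
#'
#' Applies the IIR filter forward and then backward, cancelling phase lag and
#' squaring the magnitude response. Edges are handled by odd-symmetric signal
#' extension of `3 * (order + 1)` samples, with step-matched initial filter
#' states.
#'
#' @param b,a transfer function coefficients from [butter_lowpass()].
#' @param x numeric vector to filter.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zerophase <- function(b, a, x) {
  npad <- 3L * (length(a) - 1L + 1L)
  if (length(x) <= npad) {
    stop(sprintf("series too short for zero-phase filtering (need > %d samples)",
                 npad), call. = FALSE)
  }
  head_ext <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  tail_ext <- 2 * x[length(x)] - x[seq(length(x) - 1L, length(x) - npad)]
  xe <- c(head_ext, x, tail_ext)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(npad + 1L, npad + length(x))]
}

#' Low-pass filter all channels of a landmark series
#'
#' Each coordinate channel is filtered independently with a zero-phase
#' (forward-backward) Butterworth low-pass. This is the standard smoothing
#' step for noisy pose-estimation trajectories: a 3 Hz cutoff sits above the
#' human gait frequency band (0.5-1.5 Hz), so the motion patterns used for
#' event detection are preserved while frame-to-frame jitter is removed.
#' Because the filter is applied twice, the effective -3 dB point is slightly
#' below the nominal cutoff (about 2.4 Hz for a nominal 3 Hz).
#'
#' @param series a [landmark_series()].
#' @param cutoff cutoff frequency in Hz (default 3).
#' @param order filter order (default 2, i.e. effective order 4 over both
#'   passes).
#' @return The filtered [landmark_series()]; length, fps and units unchanged.
#' @export
butterworth_lowpass <- function(series, cutoff = 3, order = 2L) {
  if (cutoff >= series$fps / 2) {
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff, series$fps / 2), call. = FALSE)
  }
  if (anyNA(series$coords)) {
    stop("series contains missing samples; run fill_gaps() first", call. = FALSE)
  }
  coef <- butter_lowpass(cutoff, series$fps, order)
  series$coords[] <- lapply(series$coords, function(v) {
    filtfilt_zerophase(coef$b, coef$a, v)
  })
  series
}
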