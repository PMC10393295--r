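# Butterworth low-pass design + zero-phase filtering.
# Design follows the classic analog-prototype -> frequency-prewarp ->
# bilinear-transform route; filtering is forward-backward with odd-reflection
# padding, so the passband gain is |H|^2 (0.5 at the cutoff frequency).

# polynomial coefficients (highest order first) from complex roots
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0i) - c(0i, p * x)
  p
}

#' Butterworth low-pass filter coefficients
#'
#' Designs a digital Butterworth low-pass filter by bilinear transform of the
#' analog prototype, returning transfer-function coefficients `b` (numerator)
#' and `a` (denominator), `a[1] = 1`.
#'
#' @param order filter order (default 5).
#' @param cutoff cutoff frequency in Hz (-3 dB point of a single pass).
#' @param fs sampling rate in Hz; `cutoff` must be below `fs/2`.
#' @return list with numeric vectors `b` and `a` of length `order + 1`.
#' @export
butter_lowpass <- function(order = 5, cutoff, fs) {
  if (order < 1) invalid_argument("order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2)
    invalid_argument("cutoff must lie strictly between 0 and the Nyquist frequency")
  wn <- cutoff / (fs / 2)
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 4                      # internal sampling rate 2 -> 2*fs = 4
  warped <- 2 * fs2 / 2 * tan(pi * wn / 2)
  p <- warped * p
  gain <- warped^order
  pz <- (fs2 + p) / (fs2 - p)   # bilinear transform
  kz <- Re(gain / prod(fs2 - p))
  b <- kz * Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a / a[1])
}

# steady-state initial filter state for a unit step (lfilter_zi)
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  if (n == 1) return(numeric(0))
  # companion matrix of a (a[1] == 1)
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1] / a[1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  iminus <- diag(n - 1) - t(comp)
  rhs <- b[-1] - a[-1] * b[1]
  solve(iminus, rhs)
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (doubling the attenuation and
#' cancelling phase distortion). The signal is extended at both ends by
#' odd reflection over `3 * order` samples before filtering, and the filter
#' state is initialized at its step steady state, suppressing edge
#' transients.
#'
#' @param b,a transfer-function coefficients, e.g. from [butter_lowpass()].
#' @param x numeric signal vector.
#' @param pad_len padding length; default `3 * (max(length(a), length(b)) - 1)`.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt <- function(b, a, x, pad_len = NULL) {
  n <- length(x)
  ord <- max(length(a), length(b)) - 1
  if (is.null(pad_len)) pad_len <- 3 * ord
  if (pad_len >= n)
    invalid_argument("signal too short for the requested edge padding")
  ext <- c(2 * x[1] - x[(pad_len + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad_len)])
  zi <- lfilter_zi(b, a)
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .iir_filter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(pad_len + 1):(pad_len + n)]
}
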