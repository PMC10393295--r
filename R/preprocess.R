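# Preprocessing: zero-phase low-pass filtering, channel downsampling,
# trial averaging, baseline subtraction and bilinear regridding onto the
# common analysis grid.

#' Low-pass filter a laminar recording
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter to
#' every channel. Because of the two passes, the amplitude response at the
#' cutoff frequency is 0.5.
#'
#' @param rec a [laminar_recording()].
#' @param cutoff cutoff frequency in Hz (default 500).
#' @param order filter order (default 5).
#' @return The filtered recording (same shape).
#' @export
lowpass_filter <- function(rec, cutoff = 500, order = 5) {
  stopifnot(inherits(rec, "laminar_recording"))
  if (cutoff >= rec$fs / 2)
    invalid_argument("cutoff must be below the Nyquist frequency fs/2")
  co <- butter_lowpass(order, cutoff, rec$fs)
  out <- rec
  out$lfp <- t(apply(rec$lfp, 1, function(x) filtfilt(co$b, co$a, x)))
  out
}

#' Spatially downsample channels to a target pitch
#'
#' Retains every (`target_pitch` / native pitch)-th channel, starting from
#' the deepest channel, e.g. every other electrode when going from 20 um to
#' 40 um pitch. The native pitch must divide the target pitch.
#'
#' @param rec a [laminar_recording()] with uniform channel pitch.
#' @param target_pitch desired pitch in um (default 40).
#' @return The downsampled recording.
#' @export
select_channels <- function(rec, target_pitch = 40) {
  stopifnot(inherits(rec, "laminar_recording"))
  pitch <- diff(rec$depths)
  native <- abs(pitch[1])
  if (max(abs(abs(pitch) - native)) > 1e-6)
    invalid_argument("channel pitch is not uniform")
  step <- target_pitch / native
  if (abs(step - round(step)) > 1e-9 || step < 1)
    invalid_argument("native pitch must divide target_pitch")
  step <- as.integer(round(step))
  n <- length(rec$depths)
  # start from the deepest channel
  deepest <- which.max(rec$depths)
  idx <- if (deepest == n) rev(seq(n, 1, by = -step)) else seq(1, n, by = step)
  out <- rec
  out$lfp <- rec$lfp[idx, , drop = FALSE]
  out$depths <- rec$depths[idx]
  if (!is.null(rec$layer)) out$layer <- rec$layer[idx]
  if (!is.null(rec$area) && length(rec$area) == n) out$area <- rec$area[idx]
  out
}

#' Trial-average a recording over a peristimulus window
#'
#' Extracts the window around every trial onset and averages across trials;
#' the result's time axis is ms relative to stimulus onset.
#'
#' @param rec a [laminar_recording()].
#' @param window `c(t0, t1)` in ms relative to onset.
#' @return A [grid_pattern()] (channels x window samples) of averaged LFP.
#' @export
trial_average <- function(rec, window = c(-250, 100)) {
  stopifnot(inherits(rec, "laminar_recording"))
  offs <- seq(round(window[1] / 1000 * rec$fs), round(window[2] / 1000 * rec$fs))
  t_ms <- offs / rec$fs * 1000
  onset_idx <- round(rec$trial_onsets * rec$fs) + 1
  nsamp <- ncol(rec$lfp)
  bad <- which(onset_idx + offs[1] < 1 | onset_idx + offs[length(offs)] > nsamp)
  if (length(bad))
    invalid_argument(sprintf(
      "window exceeds recording bounds for trial(s): %s",
      paste(bad, collapse = ", ")))
  acc <- matrix(0, nrow(rec$lfp), length(offs))
  for (k in seq_along(onset_idx))
    acc <- acc + rec$lfp[, onset_idx[k] + offs, drop = FALSE]
  grid_pattern(acc / length(onset_idx), rec$depths, t_ms, units = "LFP")
}

#' Subtract the pre-stimulus baseline
#'
#' Removes each channel's mean over the baseline window. Idempotent.
#'
#' @param pattern a [grid_pattern()].
#' @param baseline_window `c(t0, t1)` in ms; samples with
#'   `t0 <= t < t1` form the baseline (default `[-250, 0)`).
#' @return The baseline-subtracted pattern.
#' @export
baseline_subtract <- function(pattern, baseline_window = c(-250, 0)) {
  stopifnot(inherits(pattern, "grid_pattern"))
  sel <- pattern$time_axis >= baseline_window[1] &
    pattern$time_axis < baseline_window[2]
  if (!any(sel))
    invalid_argument("baseline window contains no samples")
  out <- pattern
  out$values <- pattern$values - rowMeans(pattern$values[, sel, drop = FALSE])
  out
}

#' Crop a grid pattern in time
#'
#' @param pattern a [grid_pattern()].
#' @param window `c(t0, t1)` ms; samples with `t0 <= t <= t1` are kept.
#' @return The cropped pattern.
#' @export
crop_time <- function(pattern, window) {
  sel <- pattern$time_axis >= window[1] & pattern$time_axis <= window[2]
  if (sum(sel) < 2) invalid_argument("cropped window has fewer than 2 samples")
  p <- pattern
  p$values <- pattern$values[, sel, drop = FALSE]
  p$time_axis <- pattern$time_axis[sel]
  p
}

#' Bilinear interpolation onto the common analysis grid
#'
#' Resamples a pattern onto `M` uniformly spaced depths and `K` uniformly
#' spaced times spanning the input ranges (endpoints preserved). Bilinear
#' interpolation is exact on functions linear in each coordinate, and the
#' operation is idempotent on its own output grid.
#'
#' @param pattern a [grid_pattern()] (at least 2 x 2).
#' @param M,K output grid sizes (defaults 30 x 100).
#' @return The regridded pattern (same class as the input).
#' @export
interpolate_grid <- function(pattern, M = 30, K = 100) {
  stopifnot(inherits(pattern, "grid_pattern"))
  if (M < 2 || K < 2) invalid_argument("M and K must both be >= 2")
  dz <- seq(min(pattern$depth_axis), max(pattern$depth_axis), length.out = M)
  tz <- seq(min(pattern$time_axis), max(pattern$time_axis), length.out = K)
  # separable bilinear: time axis first, then depth axis
  tmp <- t(apply(pattern$values, 1, function(row)
    approx(pattern$time_axis, row, xout = tz)$y))
  out <- apply(tmp, 2, function(col)
    approx(pattern$depth_axis, col, xout = dz)$y)
  if (inherits(pattern, "csd_pattern"))
    csd_pattern(out, dz, tz, units = pattern$units)
  else grid_pattern(out, dz, tz, units = pattern$units)
}

#' Resample a pattern onto the grid of a reference pattern
#'
#' Bilinear interpolation onto the reference axes; points outside the input
#' range take the nearest edge value.
#'
#' @param pattern a [grid_pattern()].
#' @param ref a [grid_pattern()] providing the target axes.
#' @return The resampled pattern on `ref`'s grid.
#' @export
regrid_to <- function(pattern, ref) {
  tmp <- t(apply(pattern$values, 1, function(row)
    approx(pattern$time_axis, row, xout = ref$time_axis, rule = 2)$y))
  out <- apply(tmp, 2, function(col)
    approx(pattern$depth_axis, col, xout = ref$depth_axis, rule = 2)$y)
  if (inherits(pattern, "csd_pattern"))
    csd_pattern(out, ref$depth_axis, ref$time_axis, units = pattern$units)
  else grid_pattern(out, ref$depth_axis, ref$time_axis, units = pattern$units)
}
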