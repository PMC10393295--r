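#' Laminar multichannel recording
#'
#' Container for a depth-resolved extracellular recording: an LFP matrix
#' (channels by samples), the physical depth of each channel, the sampling
#' rate, and stimulus (trial) onset times. Depths are micrometres below the
#' cortical surface and must be strictly monotone; channels containing NaN
#' must be dropped before construction.
#'
#' @param lfp numeric matrix, channels x samples (microvolt-scale units).
#' @param depths numeric vector, one depth (um) per channel, strictly monotone.
#' @param fs sampling rate in Hz.
#' @param trial_onsets stimulus onset times in seconds from recording start.
#' @param area,layer optional per-channel labels.
#' @return An object of class `laminar_recording`.
#' @export
laminar_recording <- function(lfp, depths, fs, trial_onsets,
                              area = NULL, layer = NULL) {
  lfp <- as.matrix(lfp)
  if (nrow(lfp) != length(depths))
    invalid_argument("number of LFP rows must equal length(depths)")
  if (!is_strictly_monotone(depths))
    invalid_argument("channel depths must be strictly monotone")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    invalid_argument("fs must be a single positive number")
  if (anyNA(lfp))
    invalid_argument("LFP contains NaN/NA; drop bad channels at ingest")
  structure(list(lfp = lfp, depths = as.numeric(depths), fs = fs,
                 trial_onsets = as.numeric(trial_onsets),
                 area = area, layer = layer),
            class = "laminar_recording")
}

#' @export
print.laminar_recording <- function(x, ...) {
  cat(sprintf("<laminar_recording> %d channels x %d samples @ %g Hz, %d trials\n",
              nrow(x$lfp), ncol(x$lfp), x$fs, length(x$trial_onsets)))
  cat(sprintf("  depths: %g..%g um (pitch %g um)\n",
              min(x$depths), max(x$depths), median(diff(x$depths))))
  invisible(x)
}

#' Depth-time grid pattern
#'
#' A matrix of values sampled on a rectangular depth (um) by time (ms,
#' relative to stimulus onset) grid. Used both for trial-averaged LFP and
#' for CSD patterns.
#'
#' @param values numeric matrix, depths x times.
#' @param depth_axis depth coordinates (um), strictly monotone, length nrow.
#' @param time_axis time coordinates (ms), strictly monotone, length ncol.
#' @param units free-text unit label stored as an attribute.
#' @return An object of class `grid_pattern`.
#' @export
grid_pattern <- function(values, depth_axis, time_axis, units = "") {
  values <- as.matrix(values)
  if (nrow(values) != length(depth_axis) || ncol(values) != length(time_axis))
    invalid_argument("grid_pattern: axis lengths must match value dimensions")
  if (length(depth_axis) < 2 || length(time_axis) < 2)
    invalid_argument("grid_pattern: both axes need at least 2 points")
  if (!is_strictly_monotone(depth_axis) || !is_strictly_monotone(time_axis))
    invalid_argument("grid_pattern: axes must be strictly monotone")
  if (any(!is.finite(values)))
    invalid_argument("grid_pattern: values must be finite")
  structure(list(values = values, depth_axis = as.numeric(depth_axis),
                 time_axis = as.numeric(time_axis), units = units),
            class = "grid_pattern")
}

#' Depth-time CSD pattern
#'
#' A [grid_pattern()] carrying signed current-source-density values
#' (negative = sink, positive = source).
#'
#' @inheritParams grid_pattern
#' @return An object of class `csd_pattern` (inherits `grid_pattern`).
#' @export
csd_pattern <- function(values, depth_axis, time_axis,
                        units = "planar CSD (A/m^2)") {
  p <- grid_pattern(values, depth_axis, time_axis, units = units)
  class(p) <- c("csd_pattern", class(p))
  p
}

#' @export
print.grid_pattern <- function(x, ...) {
  cat(sprintf("<%s> %d depths x %d times; depth %g..%g um, time %g..%g ms\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              min(x$depth_axis), max(x$depth_axis),
              min(x$time_axis), max(x$time_axis)))
  invisible(x)
}

same_grid <- function(p1, p2, tol = 1e-9) {
  all(dim(p1$values) == dim(p2$values)) &&
    max(abs(p1$depth_axis - p2$depth_axis)) <= tol &&
    max(abs(p1$time_axis - p2$time_axis)) <= tol
}

#' Default cortical layer boundaries
#'
#' Depth bands (um below pia) delimiting layers 1, 2/3, 4, 5 and 6 for a
#' mouse V1-like column of total thickness 860 um.
#'
#' @return Named numeric vector of lower boundaries.
#' @export
layer_boundaries <- function() {
  c("1" = 0, "2/3" = 100, "4" = 310, "5" = 430, "6" = 650, bottom = 860)
}

#' Assign a cortical layer label to a depth
#'
#' @param depth depth(s) in um below the cortical surface.
#' @return Character vector of layer labels ("1", "2/3", "4", "5", "6").
#' @export
assign_layer <- function(depth) {
  bnd <- layer_boundaries()
  labs <- names(bnd)[-length(bnd)]
  idx <- findInterval(depth, bnd, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > length(labs)] <- length(labs)
  labs[idx]
}

# ---- plain-text serialization (CSV/JSON stand-in for a binary container) ----

#' Write / read a grid pattern as plain text
#'
#' The pattern is stored as a JSON object with fields `values` (row-major
#' list of rows), `depth_axis`, `time_axis`, `units` and `class`.
#'
#' @param pattern a [grid_pattern()] or [csd_pattern()].
#' @param path file path.
#' @return `write_grid_pattern` returns `path` invisibly;
#'   `read_grid_pattern` returns the pattern.
#' @export
write_grid_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "grid_pattern"))
  obj <- list(class = class(pattern)[1],
              depth_axis = pattern$depth_axis,
              time_axis = pattern$time_axis,
              units = pattern$units,
              values = unname(apply(pattern$values, 1, c, simplify = FALSE)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_grid_pattern
#' @export
read_grid_pattern <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- if (is.matrix(obj$values)) obj$values
  else do.call(rbind, lapply(obj$values, as.numeric))
  if (identical(obj$class, "csd_pattern"))
    csd_pattern(vals, obj$depth_axis, obj$time_axis, units = obj$units)
  else grid_pattern(vals, obj$depth_axis, obj$time_axis, units = obj$units)
}

#' Write / read a laminar recording as plain text
#'
#' Writes `<stem>_lfp.csv` (channels x samples, no header) and
#' `<stem>_meta.json` (depths, fs, trial onsets).
#'
#' @param rec a [laminar_recording()].
#' @param stem path stem (directory + file prefix).
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns the recording.
#' @export
write_recording <- function(rec, stem) {
  stopifnot(inherits(rec, "laminar_recording"))
  utils::write.table(rec$lfp, paste0(stem, "_lfp.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(depths = rec$depths, fs = rec$fs,
                            trial_onsets = rec$trial_onsets),
                       paste0(stem, "_meta.json"), digits = NA)
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  lfp <- as.matrix(utils::read.table(paste0(stem, "_lfp.csv"), sep = ","))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"), simplifyVector = TRUE)
  laminar_recording(unname(lfp), meta$depths, meta$fs, meta$trial_onsets)
}
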