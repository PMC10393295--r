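# Synthetic cohort generator: manifests with QC flags, ground-truth CSD
# patterns built from canonical sink/source components, and forward-consistent
# surrogate LFP trials.

#' Generate a cohort manifest with QC exclusion flags
#'
#' Emulates a multi-animal Neuropixels survey in which some animals lack a
#' usable V1 LFP recording, some have probe trajectories that cannot be
#' recovered from histology, and some have no sorted V1 units. By default the
#' three exclusion sets are disjoint, matching additive exclusion arithmetic
#' (e.g. 58 - 9 - 5 = 44 animals retained for CSD, 58 - 9 - 2 = 47 for
#' spikes).
#'
#' @param n_animals cohort size.
#' @param n_missing_lfp number of animals flagged as missing V1 LFP.
#' @param n_bad_probe number of animals whose probe location is unrecoverable.
#' @param n_no_units number of animals without sorted V1 units.
#' @param n_trials flash trials per animal (>= 1).
#' @param seed master seed; fixed seed gives a byte-identical manifest.
#' @param overlap if `FALSE` (default) flag sets are drawn disjointly; if
#'   `TRUE` each flag set is drawn independently (stress-test mode).
#' @return A `data.frame` with columns `animal_id`, `has_v1_lfp`,
#'   `probe_recoverable`, `has_v1_units`, `n_trials`, `seed` (one derived
#'   seed per animal).
#' @export
generate_cohort_manifest <- function(n_animals, n_missing_lfp = 0,
                                     n_bad_probe = 0, n_no_units = 0,
                                     n_trials = 75, seed = 1,
                                     overlap = FALSE) {
  counts <- c(n_missing_lfp, n_bad_probe, n_no_units)
  if (n_animals < 1 || n_trials < 1)
    invalid_argument("n_animals and n_trials must be >= 1")
  if (any(counts < 0) || any(counts > n_animals))
    invalid_argument("flag counts must lie in [0, n_animals]")
  if (!overlap && sum(counts) > n_animals)
    invalid_argument("disjoint flag sets require sum of flag counts <= n_animals")
  with_seed(seed, {
    ids <- sprintf("animal_%03d", seq_len(n_animals))
    if (overlap) {
      miss_lfp <- sample.int(n_animals, n_missing_lfp)
      bad_probe <- sample.int(n_animals, n_bad_probe)
      no_units <- sample.int(n_animals, n_no_units)
    } else {
      pick <- sample.int(n_animals, sum(counts))
      miss_lfp <- pick[seq_len(n_missing_lfp)]
      bad_probe <- pick[n_missing_lfp + seq_len(n_bad_probe)]
      no_units <- pick[n_missing_lfp + n_bad_probe + seq_len(n_no_units)]
    }
    data.frame(animal_id = ids,
               has_v1_lfp = !(seq_len(n_animals) %in% miss_lfp),
               probe_recoverable = !(seq_len(n_animals) %in% bad_probe),
               has_v1_units = !(seq_len(n_animals) %in% no_units),
               n_trials = as.integer(n_trials),
               seed = derive_seeds(seed, n_animals),
               stringsAsFactors = FALSE)
  })
}

#' Filter a cohort manifest by analysis modality
#'
#' CSD analysis requires a recoverable probe location and a V1 LFP recording;
#' spike analysis requires a recoverable probe location and sorted V1 units.
#'
#' @param manifest a manifest from [generate_cohort_manifest()].
#' @param modality `"csd"` or `"spikes"`.
#' @return Character vector of retained `animal_id`s, in manifest order.
#' @export
filter_cohort <- function(manifest, modality = c("csd", "spikes")) {
  modality <- match.arg(modality)
  if (nrow(manifest) == 0) return(character(0))
  keep <- if (modality == "csd")
    manifest$probe_recoverable & manifest$has_v1_lfp
  else
    manifest$probe_recoverable & manifest$has_v1_units
  manifest$animal_id[keep]
}

#' Canonical CSD component table
#'
#' Reads the versioned default table of flash-evoked sink/source components:
#' an early transient L4 sink (~40 ms), a sustained L4 source (~60 ms), a
#' sustained L5/6 sink (~50 ms) and a sustained L2/3 sink (~60 ms).
#'
#' @param path optional path to an alternative component CSV.
#' @return `data.frame` with columns `name`, `polarity`, `depth_center`,
#'   `depth_sigma`, `onset`, `duration`, `peak_amplitude`, `temporal_shape`.
#' @export
canonical_components <- function(path = NULL) {
  path <- path %||% system.file("extdata", "canonical_components.csv",
                                package = "lamcsd", mustWork = TRUE)
  comp <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_components(comp)
  comp
}

validate_components <- function(comp) {
  req <- c("name", "polarity", "depth_center", "depth_sigma", "onset",
           "duration", "peak_amplitude", "temporal_shape")
  if (!all(req %in% names(comp)))
    invalid_argument("component table is missing required columns")
  if (any(comp$depth_sigma <= 0) || any(comp$duration <= 0))
    invalid_argument("component depth_sigma and duration must be positive")
  bad_sign <- (comp$polarity == "sink" & comp$peak_amplitude >= 0) |
    (comp$polarity == "source" & comp$peak_amplitude <= 0)
  if (any(bad_sign))
    invalid_argument("sink amplitudes must be negative, source amplitudes positive")
  if (!all(comp$temporal_shape %in% c("transient", "sustained")))
    invalid_argument("temporal_shape must be 'transient' or 'sustained'")
  invisible(comp)
}

#' Animal- and trial-level variability parameters
#'
#' @param animal_latency_sd per-animal component latency jitter SD (ms).
#' @param animal_depth_sd per-animal component depth jitter SD (um).
#' @param animal_amplitude_cv coefficient of variation of the per-animal
#'   global response gain (a smaller per-component wobble, one third of
#'   this value, is added on top). The default makes overall response
#'   amplitude the dominant mode of inter-animal variability, so the first
#'   principal component of a cohort explains roughly half the variance and
#'   visually matches the canonical pattern.
#' @param trial_noise_sd white-noise SD added per trial, in the LFP units
#'   produced by the disc forward operator. The default matches the RMS of
#'   the canonical evoked LFP (single-trial SNR near 1, so the evoked
#'   pattern emerges cleanly only after trial averaging).
#' @param gamma_period period of the trial gamma oscillation (ms, default 20).
#' @param gamma_amplitude amplitude of the gamma oscillation (LFP units).
#' @return A list of class `variability_spec`.
#' @export
variability_spec <- function(animal_latency_sd = 4, animal_depth_sd = 20,
                             animal_amplitude_cv = 0.5,
                             trial_noise_sd = 0.003,
                             gamma_period = 20, gamma_amplitude = 0.002) {
  if (any(c(animal_latency_sd, animal_depth_sd, animal_amplitude_cv,
            trial_noise_sd, gamma_amplitude) < 0))
    invalid_argument("variability SDs/amplitudes must be >= 0")
  if (gamma_period <= 0) invalid_argument("gamma_period must be > 0")
  structure(list(animal_latency_sd = animal_latency_sd,
                 animal_depth_sd = animal_depth_sd,
                 animal_amplitude_cv = animal_amplitude_cv,
                 trial_noise_sd = trial_noise_sd,
                 gamma_period = gamma_period,
                 gamma_amplitude = gamma_amplitude),
            class = "variability_spec")
}

# temporal profile of one component on time axis t (ms); peak value 1
component_profile <- function(t, onset, duration, shape, rise_ms = 3) {
  if (shape == "transient") {
    exp(-(t - (onset + duration / 2))^2 / (2 * (duration / 2.355)^2))
  } else {
    stats::plogis((t - onset) / rise_ms) *
      stats::plogis((onset + duration - t) / rise_ms)
  }
}

#' Synthesize a ground-truth CSD pattern
#'
#' Sums spatio-temporal Gaussian-profile sink/source components, optionally
#' applying per-animal jitter to latency, depth and amplitude. Components
#' whose jittered depth centre falls outside the grid are clipped to the grid
#' boundary with a warning.
#'
#' @param components component table, see [canonical_components()].
#' @param depth_axis,time_axis grid coordinates (um, ms).
#' @param jitter a [variability_spec()] or `NULL` for no jitter.
#' @param seed RNG seed for the jitter draw.
#' @return A [csd_pattern()] on the requested grid.
#' @export
synth_ground_truth_csd <- function(components, depth_axis, time_axis,
                                   jitter = NULL, seed = NULL) {
  vals <- matrix(0, length(depth_axis), length(time_axis))
  if (is.null(components) || nrow(components) == 0)
    return(csd_pattern(vals, depth_axis, time_axis))
  validate_components(components)
  with_seed(seed, {
    # animals differ mainly by a shared response gain; per-component
    # amplitude wobble is a third of the global coefficient of variation
    gain <- 1
    if (!is.null(jitter) && jitter$animal_amplitude_cv > 0) {
      sdlog <- sqrt(log(1 + jitter$animal_amplitude_cv^2))
      gain <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
    for (i in seq_len(nrow(components))) {
      cm <- components[i, ]
      d0 <- cm$depth_center
      t0 <- cm$onset
      amp <- cm$peak_amplitude * gain
      if (!is.null(jitter)) {
        d0 <- d0 + rnorm(1, 0, jitter$animal_depth_sd)
        t0 <- t0 + rnorm(1, 0, jitter$animal_latency_sd)
        cv <- jitter$animal_amplitude_cv / 3
        if (cv > 0) {
          sdlog <- sqrt(log(1 + cv^2))
          amp <- amp * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }
      }
      if (d0 < min(depth_axis) || d0 > max(depth_axis)) {
        warning(sprintf("component '%s' centre clipped to grid boundary", cm$name))
        d0 <- min(max(d0, min(depth_axis)), max(depth_axis))
      }
      spatial <- exp(-(depth_axis - d0)^2 / (2 * cm$depth_sigma^2))
      temporal <- component_profile(time_axis, t0, cm$duration, cm$temporal_shape)
      vals <- vals + amp * outer(spatial, temporal)
    }
  })
  csd_pattern(vals, depth_axis, time_axis)
}

#' Synthesize forward-consistent LFP trials
#'
#' Builds a continuous laminar recording in which each trial's LFP equals the
#' disc forward operator applied to a ground-truth CSD pattern, plus a
#' gamma-band oscillation (sinusoid with random phase per trial, depth
#' envelope over the supragranular band) and white noise. The trial-averaged
#' LFP converges to `forward(truth)` as the number of trials grows.
#'
#' @param truth ground-truth [csd_pattern()]; its time axis is ms relative to
#'   flash onset. Values are linearly interpolated onto electrode depths and
#'   sample times (zero outside its time support).
#' @param electrode_depths electrode depths (um); must match `forward$depths`.
#' @param n_trials number of trials.
#' @param noise a [variability_spec()] providing trial noise parameters.
#' @param forward a forward operator from [build_forward()].
#' @param seed RNG seed.
#' @param fs sampling rate (Hz).
#' @param pre_s,post_s seconds of recording before/after each flash onset.
#' @return A [laminar_recording()] with `n_trials` onsets.
#' @export
synth_lfp_trials <- function(truth, electrode_depths, n_trials, noise,
                             forward, seed = NULL, fs = 1250,
                             pre_s = 0.3, post_s = 0.4) {
  if (length(forward$depths) != length(electrode_depths) ||
      max(abs(forward$depths - electrode_depths)) > 1e-9)
    invalid_argument("forward operator depths must match electrode_depths")
  nchan <- length(electrode_depths)
  seg <- round((pre_s + post_s) * fs)
  total <- seg * n_trials
  onsets <- pre_s + (seq_len(n_trials) - 1) * (pre_s + post_s)

  # truth resampled onto electrode depths and the per-trial sample grid
  t_rel_ms <- (seq_len(seg) - 1 - round(pre_s * fs)) / fs * 1000
  csd_e <- apply(truth$values, 2, function(col)
    approx(truth$depth_axis, col, xout = electrode_depths, rule = 2)$y)
  csd_et <- t(apply(csd_e, 1, function(row) {
    y <- approx(truth$time_axis, row, xout = t_rel_ms)$y
    y[is.na(y)] <- 0
    y
  }))
  evoked <- forward$F %*% csd_et           # channels x seg

  gamma_env <- exp(-(electrode_depths - 300)^2 / (2 * 150^2))
  # biological LFP noise is spatially smooth across a 20 um-pitch probe
  # (volume conduction); a small white component models electrode noise.
  # The smooth component stays in the well-conditioned subspace of the disc
  # operator, so trial-averaged CSD estimates remain stable.
  spat_corr <- exp(-outer(electrode_depths, electrode_depths, "-")^2 /
                     (2 * 150^2))
  cf <- chol(spat_corr + 1e-8 * diag(nchan))
  lfp <- matrix(0, nchan, total)
  with_seed(seed, {
    for (k in seq_len(n_trials)) {
      cols <- (k - 1) * seg + seq_len(seg)
      trial <- evoked
      if (noise$gamma_amplitude > 0) {
        phase <- runif(1, 0, 2 * pi)
        osc <- sin(2 * pi * t_rel_ms / noise$gamma_period + phase)
        trial <- trial + noise$gamma_amplitude * outer(gamma_env, osc)
      }
      if (noise$trial_noise_sd > 0) {
        smooth <- crossprod(cf, matrix(rnorm(nchan * seg), nchan, seg))
        white <- matrix(rnorm(nchan * seg, 0, 0.1), nchan, seg)
        trial <- trial + noise$trial_noise_sd * (smooth + white)
      }
      lfp[, cols] <- trial
    }
  })
  laminar_recording(lfp, electrode_depths, fs, onsets,
                    layer = assign_layer(electrode_depths))
}

#' Write / read a cohort manifest CSV
#'
#' Columnar text table with header
#' `animal_id,has_v1_lfp,probe_recoverable,has_v1_units,n_trials,seed`.
#'
#' @param manifest manifest data.frame.
#' @param path file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` the
#'   manifest.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(animal_id = "character"))
}
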