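# Synthetic spiking: inhomogeneous-Poisson population cohorts with trapezoid
# flash-evoked rate profiles, bimodal waveform durations, and the LGN input
# pool / assignment machinery used to build model input.

#' Population rate specification
#'
#' Describes the trial-locked firing-rate profile of one population:
#' a baseline before the flash, a linear rise to a peak at `peak_latency`,
#' a fall to a sustained plateau by the end of the initial-peak window, and a
#' return to baseline after stimulus offset (250 ms).
#'
#' @param population label, e.g. `"RS L4"` or `"FS"`.
#' @param baseline_rate,peak_rate,sustained_rate rates in spikes/s (>= 0).
#' @param peak_latency time of the evoked peak (ms after onset).
#' @param n_units number of units to generate.
#' @param waveform_duration_mode mode of the trough-to-peak duration (ms).
#' @return A list of class `population_rate_spec`.
#' @export
population_rate_spec <- function(population, baseline_rate, peak_rate,
                                 sustained_rate, peak_latency = 45,
                                 n_units = 50,
                                 waveform_duration_mode = 0.55) {
  if (any(c(baseline_rate, peak_rate, sustained_rate) < 0))
    invalid_argument("rates must be >= 0")
  if (n_units < 1) invalid_argument("n_units must be >= 1")
  structure(list(population = population, baseline_rate = baseline_rate,
                 peak_rate = peak_rate, sustained_rate = sustained_rate,
                 peak_latency = peak_latency, n_units = n_units,
                 waveform_duration_mode = waveform_duration_mode),
            class = "population_rate_spec")
}

#' Default V1 population rate specifications
#'
#' Five populations (RS per layer 2/3-6, FS pooled across layers) with a
#' fast-spiking baseline more than twice that of every regular-spiking
#' population, and bimodal waveform-duration modes (0.55 ms RS, 0.25 ms FS)
#' straddling the 0.4 ms cortical classification cutoff.
#'
#' @return List of [population_rate_spec()] objects.
#' @export
default_population_rate_specs <- function() {
  list(
    population_rate_spec("RS L2/3", 1.5, 8, 3, peak_latency = 55, n_units = 60,
                         waveform_duration_mode = 0.55),
    population_rate_spec("RS L4", 2.0, 15, 4, peak_latency = 45, n_units = 60,
                         waveform_duration_mode = 0.55),
    population_rate_spec("RS L5", 3.0, 12, 5, peak_latency = 50, n_units = 60,
                         waveform_duration_mode = 0.55),
    population_rate_spec("RS L6", 2.0, 8, 3, peak_latency = 50, n_units = 60,
                         waveform_duration_mode = 0.55),
    population_rate_spec("FS", 8.0, 30, 12, peak_latency = 45, n_units = 40,
                         waveform_duration_mode = 0.25))
}

# trapezoid rate profile in spikes/s on times t (ms relative to onset)
trapezoid_rate <- function(t, spec, rise_start = 20, sustain_start = 60,
                           offset = 250) {
  r <- rep(spec$baseline_rate, length(t))
  pk <- spec$peak_latency
  up <- t >= rise_start & t < pk
  r[up] <- spec$baseline_rate + (spec$peak_rate - spec$baseline_rate) *
    (t[up] - rise_start) / max(pk - rise_start, 1e-9)
  dn <- t >= pk & t < sustain_start
  r[dn] <- spec$peak_rate + (spec$sustained_rate - spec$peak_rate) *
    (t[dn] - pk) / max(sustain_start - pk, 1e-9)
  sus <- t >= sustain_start & t < offset
  r[sus] <- spec$sustained_rate
  r
}

# vectorized inhomogeneous-Poisson thinning for n_series independent series;
# rate_fn maps ms-relative-to-onset times to spikes/s. Returns a list of
# spike-time vectors (seconds relative to onset, 0.1 ms resolution).
sample_poisson_series <- function(rate_fn, n_series, window_s = c(-0.3, 0.4)) {
  dur <- diff(window_s)
  probe <- rate_fn(seq(window_s[1], window_s[2], length.out = 2001) * 1000)
  rmax <- max(probe)
  if (rmax <= 0) return(rep(list(numeric(0)), n_series))
  counts <- rpois(n_series, rmax * dur)
  total <- sum(counts)
  out <- rep(list(numeric(0)), n_series)
  if (total == 0) return(out)
  ts <- runif(total, window_s[1], window_s[2])
  keep <- runif(total) * rmax < rate_fn(ts * 1000)
  idx <- rep.int(seq_len(n_series), counts)[keep]
  ts <- round(ts[keep] * 1e4) / 1e4          # 0.1 ms resolution
  got <- split(ts, factor(idx, levels = seq_len(n_series)))
  lapply(got, sort)
}

#' Generate a synthetic spiking cohort for one animal
#'
#' Draws inhomogeneous-Poisson spike trains per unit and trial from each
#' population's trapezoid rate profile, and trough-to-peak waveform durations
#' from a Gaussian around each population's mode (SD 0.05 ms), so that
#' duration-based RS/FS classification recovers the intended labels for the
#' bulk of units.
#'
#' @param specs list of [population_rate_spec()].
#' @param n_trials trials per unit.
#' @param seed RNG seed; identical seeds give identical tables.
#' @param animal_id animal label attached to all units.
#' @param area area label (affects the classification cutoff downstream).
#' @param window_s trial window in seconds relative to flash onset.
#' @return A `unit_table`: list with `units` (one row per unit: `unit_id`,
#'   `animal_id`, `area`, `layer`, `duration_ms`, `population`) and `spikes`
#'   (long table `unit_id`, `trial`, `spike_time_s`), plus `n_trials`.
#' @export
synth_spike_cohort <- function(specs, n_trials, seed = NULL,
                               animal_id = "animal_001", area = "V1",
                               window_s = c(-0.3, 0.4)) {
  if (length(specs) == 0) invalid_argument("specs must be non-empty")
  units_l <- list(); spikes_l <- list(); uctr <- 0L
  with_seed(seed, {
    for (spec in specs) {
      n <- spec$n_units
      ids <- sprintf("%s_u%04d", animal_id, uctr + seq_len(n))
      uctr <- uctr + n
      layer <- if (grepl("^RS L", spec$population))
        rep(sub("^RS L", "", spec$population), n)
      else rep_len(c("2/3", "4", "5", "6"), n)     # FS spread across layers
      dur <- pmax(0.1, rnorm(n, spec$waveform_duration_mode, 0.05))
      units_l[[length(units_l) + 1L]] <- data.table::data.table(
        unit_id = ids, animal_id = animal_id, area = area, layer = layer,
        duration_ms = dur, population = spec$population)
      trains <- sample_poisson_series(function(t) trapezoid_rate(t, spec),
                                      n * n_trials, window_s)
      len <- lengths(trains)
      if (sum(len) > 0) {
        spikes_l[[length(spikes_l) + 1L]] <- data.table::data.table(
          unit_id = rep(rep(ids, each = n_trials), len),
          trial = rep(rep(seq_len(n_trials), n), len),
          spike_time_s = unlist(trains, use.names = FALSE))
      }
    }
  })
  structure(list(units = data.table::rbindlist(units_l),
                 spikes = if (length(spikes_l))
                   data.table::rbindlist(spikes_l)
                 else data.table::data.table(unit_id = character(),
                                             trial = integer(),
                                             spike_time_s = numeric()),
                 n_trials = as.integer(n_trials),
                 window_s = window_s),
            class = "unit_table")
}

#' @export
print.unit_table <- function(x, ...) {
  cat(sprintf("<unit_table> %d units, %d trials, %d spikes\n",
              nrow(x$units), x$n_trials, nrow(x$spikes)))
  invisible(x)
}

#' Combine unit tables from several animals
#'
#' @param tables list of `unit_table`s with a common trial count.
#' @return A single `unit_table`.
#' @export
bind_unit_tables <- function(tables) {
  nt <- unique(vapply(tables, `[[`, integer(1), "n_trials"))
  if (length(nt) != 1)
    invalid_argument("unit tables must share a common n_trials")
  structure(list(units = data.table::rbindlist(lapply(tables, `[[`, "units")),
                 spikes = data.table::rbindlist(lapply(tables, `[[`, "spikes")),
                 n_trials = nt, window_s = tables[[1]]$window_s),
            class = "unit_table")
}

#' Build a pool of recorded LGN spike trains
#'
#' Emulates pooling trains across recorded LGN units and trials: the pool
#' holds exactly `n_units * n_trials_recorded` spike trains drawn from the
#' template rate profile.
#'
#' @param n_units number of recorded units (e.g. 1263).
#' @param n_trials_recorded recorded trials per unit (e.g. 75).
#' @param rate_template a [population_rate_spec()]; default is an LGN-like
#'   transient profile.
#' @param seed RNG seed.
#' @param window_s train window in seconds relative to flash onset.
#' @return A `spike_train_pool`: list with `trains` (list of spike-time
#'   vectors), `unit`, `trial` indices and counts.
#' @export
build_lgn_input_pool <- function(n_units, n_trials_recorded,
                                 rate_template = NULL, seed = NULL,
                                 window_s = c(-0.25, 0.45)) {
  if (n_units < 1 || n_trials_recorded < 1)
    invalid_argument("pool requires n_units >= 1 and n_trials_recorded >= 1")
  rate_template <- rate_template %||%
    population_rate_spec("LGN", 4, 30, 8, peak_latency = 35,
                         n_units = n_units, waveform_duration_mode = 0.45)
  n_trains <- n_units * n_trials_recorded
  trains <- with_seed(seed, sample_poisson_series(
    function(t) trapezoid_rate(t, rate_template, rise_start = 15,
                               sustain_start = 50),
    n_trains, window_s))
  structure(list(trains = trains,
                 unit = rep(seq_len(n_units), each = n_trials_recorded),
                 trial = rep(seq_len(n_trials_recorded), n_units),
                 n_units = n_units, n_trials_recorded = n_trials_recorded),
            class = "spike_train_pool")
}

#' @export
print.spike_train_pool <- function(x, ...) {
  cat(sprintf("<spike_train_pool> %d trains (%d units x %d trials)\n",
              length(x$trains), x$n_units, x$n_trials_recorded))
  invisible(x)
}

#' Assign pooled spike trains to model input units
#'
#' Divides the pool into `n_subsets` subsets and, for each simulated trial,
#' samples trains with replacement from that trial's subset until every
#' target unit has a train, i.e. every one of the `n_target_units` units has
#' an assigned train in all `n_sim_trials` trials.
#'
#' @param pool a pool from [build_lgn_input_pool()].
#' @param n_target_units number of model input units (e.g. 17400).
#' @param n_sim_trials number of simulated trials (e.g. 10).
#' @param n_subsets number of pool subsets; must be >= `n_sim_trials`.
#' @param seed RNG seed.
#' @return Integer matrix `n_target_units x n_sim_trials` of pool train
#'   indices, with the subset partition attached as attribute `subset`.
#' @export
assign_input_trains <- function(pool, n_target_units, n_sim_trials,
                                n_subsets = 10, seed = NULL) {
  npool <- length(pool$trains)
  if (npool == 0) invalid_argument("empty spike-train pool")
  if (n_subsets < n_sim_trials)
    invalid_argument("n_subsets must be >= n_sim_trials")
  with_seed(seed, {
    perm <- sample.int(npool)
    subset_of <- integer(npool)
    subset_of[perm] <- rep_len(seq_len(n_subsets), npool)
    out <- matrix(0L, n_target_units, n_sim_trials)
    for (j in seq_len(n_sim_trials)) {
      cand <- which(subset_of == j)
      if (length(cand) == 0 && n_sim_trials == 1) cand <- seq_len(npool)
      if (length(cand) == 0)
        invalid_argument("a pool subset is empty; reduce n_subsets")
      out[, j] <- cand[sample.int(length(cand), n_target_units,
                                  replace = TRUE)]
    }
    attr(out, "subset") <- subset_of
    out
  })
}

#' Write / read a spike table as a long CSV
#'
#' Header: `unit_id,animal_id,area,layer,duration_ms,trial,spike_time_s`.
#' Units without spikes appear with an `NA` trial row so the unit roster
#' survives the round trip.
#'
#' @param ut a `unit_table`.
#' @param path file path.
#' @return `write_unit_table` returns `path`; `read_unit_table` the table.
#' @export
write_unit_table <- function(ut, path) {
  spikes <- merge(ut$spikes, ut$units, by = "unit_id", all.y = TRUE)
  cols <- c("unit_id", "animal_id", "area", "layer", "duration_ms",
            "trial", "spike_time_s")
  data.table::fwrite(spikes[, cols, with = FALSE], path)
  invisible(path)
}

#' @rdname write_unit_table
#' @param n_trials trial count (not recoverable from the CSV when trailing
#'   trials are silent).
#' @export
read_unit_table <- function(path, n_trials) {
  long <- data.table::fread(path, colClasses = list(character = "layer"))
  units <- unique(long[, c("unit_id", "animal_id", "area", "layer",
                           "duration_ms"), with = FALSE])
  units$population <- NA_character_
  spikes <- long[!is.na(long$trial),
                 c("unit_id", "trial", "spike_time_s"), with = FALSE]
  structure(list(units = units, spikes = spikes,
                 n_trials = as.integer(n_trials), window_s = NULL),
            class = "unit_table")
}
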