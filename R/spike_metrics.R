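# Spiking statistics: RS/FS classification by waveform duration, population
# firing rates (1 ms bins, Gaussian-smoothed), KS similarity, rate
# correlation, leave-one-out cohort comparison, outlier assessment, and
# unit-level feature moments.

#' Gaussian smoothing of a 1-D signal
#'
#' Convolution with a truncated Gaussian kernel (radius `truncate * sigma`
#' bins) under reflecting boundary conditions.
#'
#' @param x numeric vector.
#' @param sigma kernel SD in bins.
#' @param truncate kernel truncation radius in SDs (default 4).
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth <- function(x, sigma, truncate = 4) {
  if (sigma <= 0) return(x)
  r <- ceiling(truncate * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  # reflect padding (edge value included)
  front <- if (r > 0) x[pmin(r:1, n)] else numeric(0)
  back <- if (r > 0) x[pmax(n - (1:r) + 1, 1)] else numeric(0)
  ext <- c(front, x, back)
  stats::convolve(ext, rev(k), type = "filter")
}

#' Classify units as regular- or fast-spiking
#'
#' Uses the trough-to-peak waveform duration with an area-specific cutoff:
#' 0.4 ms for cortical areas (V1, LM), 0.3 ms for LGN. A unit is FS iff its
#' duration is strictly below the cutoff; a duration exactly at the cutoff is
#' classified RS.
#'
#' @param duration trough-to-peak duration(s) in ms (> 0).
#' @param area area label(s): "V1", "LM" or "LGN" (recycled).
#' @return Character vector of "RS"/"FS".
#' @export
classify_rs_fs <- function(duration, area) {
  if (any(duration <= 0)) invalid_argument("durations must be positive")
  area <- rep_len(area, length(duration))
  if (!all(area %in% c("V1", "LM", "LGN")))
    invalid_argument("unknown area; expected V1, LM or LGN")
  cutoff <- ifelse(area == "LGN", 0.3, 0.4)
  ifelse(duration < cutoff, "FS", "RS")
}

# population label per unit: FS pooled across layers, RS split by layer
population_labels <- function(units) {
  cls <- classify_rs_fs(units$duration_ms, units$area)
  ifelse(cls == "FS", "FS", paste0("RS L", units$layer))
}

#' Analysis time windows
#'
#' The baseline window covers the 250 ms before flash onset, the initial
#' peak window 35-60 ms and the sustained window 60-100 ms after onset.
#' Windows are half-open `[t0, t1)` and must not overlap.
#'
#' @param baseline,peak,sustained `c(t0, t1)` in ms.
#' @return Named list of windows.
#' @export
window_set <- function(baseline = c(-250, 0), peak = c(35, 60),
                       sustained = c(60, 100)) {
  w <- list(baseline = baseline, peak = peak, sustained = sustained)
  ord <- order(vapply(w, `[`, 1, 1))
  ws <- w[ord]
  for (i in seq_len(length(ws) - 1))
    if (ws[[i]][2] > ws[[i + 1]][1])
      invalid_argument("windows must not overlap")
  w
}

#' Trial- and unit-averaged population firing rate
#'
#' Counts spikes in 1 ms bins, averages over units and trials, converts to
#' spikes/s and smooths with a Gaussian kernel (sigma in bins).
#'
#' @param ut a `unit_table` (see [synth_spike_cohort()]).
#' @param unit_ids units to include (default: all).
#' @param window `c(t0, t1)` ms relative to onset.
#' @param sigma_bins Gaussian smoothing SD in 1 ms bins (default 2).
#' @param population optional label stored in the result.
#' @return A `population_rate`: list with bin centres `t` (ms) and `rate`
#'   (spikes/s).
#' @export
population_rate <- function(ut, unit_ids = NULL, window = c(-250, 250),
                            sigma_bins = 2, population = NULL) {
  unit_ids <- unit_ids %||% ut$units$unit_id
  if (length(unit_ids) < 1) invalid_argument("empty population")
  edges <- seq(window[1], window[2], by = 1)
  sp <- ut$spikes[ut$spikes$unit_id %in% unit_ids, ]
  tms <- sp$spike_time_s * 1000
  tms <- tms[tms >= window[1] & tms < window[2]]
  counts <- if (length(tms))
    tabulate(findInterval(tms, edges), nbins = length(edges) - 1)
  else rep(0, length(edges) - 1)
  rate <- counts / (length(unit_ids) * ut$n_trials * 1e-3)
  structure(list(t = edges[-length(edges)] + 0.5,
                 rate = gaussian_smooth(rate, sigma_bins),
                 raw_rate = rate,
                 population = population, n_units = length(unit_ids)),
            class = "population_rate")
}

#' Per-unit mean firing rates in a window
#'
#' Mean rate of each unit over trials within `[t0, t1)` ms; units with no
#' spikes contribute zero. This is the per-cell distribution entering the KS
#' similarity.
#'
#' @param ut a `unit_table`.
#' @param window `c(t0, t1)` ms.
#' @param unit_ids units to include (default all).
#' @return Named numeric vector of rates (spikes/s).
#' @export
window_mean_rates <- function(ut, window, unit_ids = NULL) {
  unit_ids <- unit_ids %||% ut$units$unit_id
  # clip to the recorded span so rates stay unbiased for short recordings
  if (!is.null(ut$window_s)) {
    window <- c(max(window[1], ut$window_s[1] * 1000),
                min(window[2], ut$window_s[2] * 1000))
    if (diff(window) <= 0)
      invalid_argument("window does not overlap the recorded span")
  }
  sp <- ut$spikes[ut$spikes$unit_id %in% unit_ids, ]
  tms <- sp$spike_time_s * 1000
  sel <- tms >= window[1] & tms < window[2]
  n <- table(factor(sp$unit_id[sel], levels = unit_ids))
  setNames(as.numeric(n) / (ut$n_trials * diff(window) * 1e-3), unit_ids)
}

#' Kolmogorov-Smirnov similarity between two rate samples
#'
#' One minus the two-sample KS statistic: 1 for identical samples, 0 for
#' samples with disjoint supports.
#'
#' @param a,b non-empty numeric samples (per-cell mean rates).
#' @return Similarity in `[0, 1]`.
#' @export
ks_similarity <- function(a, b) {
  if (length(a) == 0 || length(b) == 0)
    invalid_argument("samples must be non-empty")
  1 - unname(suppressWarnings(ks.test(a, b, exact = FALSE))$statistic)
}

#' Pearson correlation between two population rates
#'
#' @param a,b `population_rate` objects on the same time grid.
#' @param window `c(t0, t1)` ms over which to correlate (default 0-100,
#'   inclusive).
#' @return Pearson r.
#' @export
rate_correlation <- function(a, b, window = c(0, 100)) {
  if (length(a$t) != length(b$t) || max(abs(a$t - b$t)) > 1e-9)
    invalid_argument("population rates must share a common time grid")
  sel <- a$t >= window[1] & a$t <= window[2]
  x <- a$rate[sel]; y <- b$rate[sel]
  if (sd(x) == 0 || sd(y) == 0)
    stop_lamcsd("zero-variance rate in correlation window",
                "lamcsd_undefined_correlation")
  cor(x, y)
}

#' Leave-one-out comparison of each animal against the cohort
#'
#' For each population (RS per layer, FS pooled) and each animal with at
#' least `min_cells` cells in that population, compares the animal to the
#' pooled remaining cohort: KS similarities of per-cell rates in the
#' baseline / peak / sustained windows (`metric = "ks"`), or the Pearson
#' correlation of the population rate time courses over 0-100 ms
#' (`metric = "corr"`).
#'
#' @param ut a combined `unit_table` covering >= 2 animals.
#' @param metric `"ks"` or `"corr"`.
#' @param windows a [window_set()].
#' @param min_cells minimum cells per animal and population (default 10).
#' @param sigma_bins smoothing for population rates (corr metric).
#' @return data.frame of per-animal, per-population scores (`KSS_b`,
#'   `KSS_p`, `KSS_s` or `r`), plus skipped entries recorded in the
#'   `skipped` attribute.
#' @export
leave_one_out_compare <- function(ut, metric = c("ks", "corr"),
                                  windows = window_set(), min_cells = 10,
                                  sigma_bins = 2) {
  metric <- match.arg(metric)
  units <- as.data.frame(ut$units)
  units$pop <- population_labels(units)
  animals <- unique(units$animal_id)
  if (length(animals) < 2) invalid_argument("need at least 2 animals")
  rows <- list(); skipped <- list()
  for (pop in sort(unique(units$pop))) {
    upop <- units[units$pop == pop, ]
    any_eligible <- FALSE
    for (an in animals) {
      mine <- upop$unit_id[upop$animal_id == an]
      rest <- upop$unit_id[upop$animal_id != an]
      if (length(mine) < min_cells) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          animal = an, population = pop, n_cells = length(mine),
          reason = sprintf("fewer than %d cells", min_cells))
        next
      }
      if (length(rest) == 0) next
      any_eligible <- TRUE
      if (metric == "ks") {
        kss <- vapply(windows, function(w)
          ks_similarity(window_mean_rates(ut, w, mine),
                        window_mean_rates(ut, w, rest)), 1.0)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, population = pop, n_cells = length(mine),
          KSS_b = kss[["baseline"]], KSS_p = kss[["peak"]],
          KSS_s = kss[["sustained"]])
      } else {
        ra <- population_rate(ut, mine, sigma_bins = sigma_bins)
        rb <- population_rate(ut, rest, sigma_bins = sigma_bins)
        r <- tryCatch(rate_correlation(ra, rb),
                      lamcsd_undefined_correlation = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, population = pop, n_cells = length(mine), r = r)
      }
    }
    if (!any_eligible)
      warning(sprintf("no animal meets the %d-cell criterion in population %s",
                      min_cells, pop))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
  else data.frame()
  out
}

#' Assess whether a model score lies within the cohort range
#'
#' Uses Tukey boxplot whiskers (most extreme cohort values within 1.5 IQR of
#' the quartiles); the verdict against the raw min-max range is also
#' reported.
#'
#' @param model_score scalar score for the model.
#' @param cohort_scores non-empty numeric cohort scores.
#' @return List with `verdict` ("within"/"outlier", whisker convention),
#'   `verdict_raw` (raw range convention), whisker bounds and raw range.
#' @export
outlier_assessment <- function(model_score, cohort_scores) {
  cohort_scores <- cohort_scores[is.finite(cohort_scores)]
  if (length(cohort_scores) == 0)
    invalid_argument("cohort_scores must be non-empty")
  q <- quantile(cohort_scores, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  lo_cand <- cohort_scores[cohort_scores >= q[1] - 1.5 * iqr]
  hi_cand <- cohort_scores[cohort_scores <= q[2] + 1.5 * iqr]
  lo <- min(lo_cand); hi <- max(hi_cand)
  list(verdict = if (model_score >= lo && model_score <= hi) "within"
       else "outlier",
       verdict_raw = if (model_score >= min(cohort_scores) &&
                         model_score <= max(cohort_scores)) "within"
       else "outlier",
       whisker_low = lo, whisker_high = hi,
       min = min(cohort_scores), max = max(cohort_scores))
}

#' Moments of unit-level response features
#'
#' Computes each unit's smoothed rate (same 1 ms binning and Gaussian
#' smoothing as [population_rate()], applied to the single unit), extracts a
#' feature in the 0-100 ms response window -- `peak_rate` (maximum),
#' `peak_latency` (time of the maximum, ms) or `max_curvature` (maximum
#' second finite difference) -- and returns the first four moments per
#' population (mean, SD, skewness, excess kurtosis; plain moment
#' estimators). Constant samples yield `NaN` skewness/kurtosis with a
#' warning.
#'
#' @param ut a `unit_table`.
#' @param feature `"peak_rate"`, `"peak_latency"` or `"max_curvature"`.
#' @param window response window in ms (default 0-100).
#' @param sigma_bins smoothing SD in bins (default 2).
#' @return data.frame with one row per population: n, mean, sd, skewness,
#'   kurtosis_excess.
#' @export
unit_feature_moments <- function(ut, feature = c("peak_rate", "peak_latency",
                                                 "max_curvature"),
                                 window = c(0, 100), sigma_bins = 2) {
  feature <- match.arg(feature)
  units <- as.data.frame(ut$units)
  units$pop <- population_labels(units)
  feat <- vapply(units$unit_id, function(uid) {
    pr <- population_rate(ut, uid, window = c(window[1] - 10, window[2] + 10),
                          sigma_bins = sigma_bins)
    sel <- pr$t >= window[1] & pr$t <= window[2]
    r <- pr$rate[sel]
    switch(feature,
           peak_rate = max(r),
           peak_latency = pr$t[sel][which.max(r)],
           max_curvature = if (length(r) >= 3) max(diff(r, differences = 2))
           else NA_real_)
  }, 1.0)
  pops <- split(feat, units$pop)
  pops <- pops[vapply(pops, length, 1L) >= 2]
  out <- do.call(rbind, lapply(names(pops), function(p) {
    x <- pops[[p]]
    m <- mean(x)
    m2 <- mean((x - m)^2)
    if (m2 == 0) {
      warning(sprintf("constant feature in population %s; higher moments NaN", p))
      sk <- NaN; ku <- NaN
    } else {
      sk <- mean((x - m)^3) / m2^1.5
      ku <- mean((x - m)^4) / m2^2 - 3
    }
    data.frame(population = p, n = length(x), mean = m, sd = sqrt(m2),
               skewness = sk, kurtosis_excess = ku)
  }))
  rownames(out) <- NULL
  out
}
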