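# Pipeline orchestration: generate -> preprocess -> iCSD -> canonical ->
# WD / spike metrics -> model evaluation -> JSON summary.

#' Default run configuration
#'
#' Every analysis constant appears exactly once here: 500 Hz order-5 low-pass,
#' 40 um channel pitch, delta-iCSD radii by context (400 um model / 800 um
#' experiment), 30 x 100 analysis grid over 0-100 ms, baseline / peak /
#' sustained windows, 0.4 / 0.3 ms RS-FS cutoffs (in [classify_rs_fs()]),
#' sigma = 2 bins rate smoothing and the 10-cell criterion.
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed = 1, outdir = tempfile("lamcsd_run_")) {
  list(seed = seed, outdir = outdir,
       n_animals = 58, n_missing_lfp = 5, n_bad_probe = 9, n_no_units = 2,
       n_trials = 75,
       electrode_pitch = 20, n_electrodes = 44,
       filter_cutoff = 500, filter_order = 5, target_pitch = 40,
       fs = 1250,
       icsd_context = "experiment", sigma = 0.3,
       grid_M = 30, grid_K = 100,
       analysis_window = c(0, 100), average_window = c(-250, 100),
       baseline_window = c(-250, 0),
       sigma_bins = 2, min_cells = 10,
       spike_unit_scale = 1,
       model_presets = c("original", "final"),
       model_n_trials = 10, model_units_per_pop = 40,
       do_pairwise = TRUE)
}

#' Read / write a flat run configuration
#'
#' Flat key-value text (JSON mapping); unknown keys are rejected, missing
#' keys fall back to [default_config()] values.
#'
#' @param path config file path.
#' @param config configuration list.
#' @return `read_run_config` returns the merged, validated configuration.
#' @export
read_run_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    invalid_argument(sprintf("unknown config key(s): %s",
                             paste(bad, collapse = ", ")))
  base[names(user)] <- user
  validate_config(base)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

validate_config <- function(config) {
  stopifnot(config$n_animals >= 1, config$n_trials >= 1,
            config$grid_M >= 2, config$grid_K >= 2,
            config$filter_cutoff < config$fs / 2)
  config
}

# per-animal synthetic acquisition + preprocessing + iCSD -> 30x100 pattern
animal_csd_pattern <- function(config, animal_seed, jitter = NULL) {
  depths <- (seq_len(config$n_electrodes) - 1) * config$electrode_pitch
  comp <- canonical_components()
  jitter <- jitter %||% variability_spec()
  seeds <- derive_seeds(animal_seed, 2)
  truth <- synth_ground_truth_csd(comp, depths, seq(-50, 250, by = 2),
                                  jitter = jitter, seed = seeds[1])
  fwd_native <- build_forward(depths, context = config$icsd_context,
                              sigma = config$sigma)
  rec <- synth_lfp_trials(truth, depths, config$n_trials, jitter,
                          fwd_native, seed = seeds[2], fs = config$fs)
  rec <- lowpass_filter(rec, config$filter_cutoff, config$filter_order)
  rec <- select_channels(rec, config$target_pitch)
  avg <- trial_average(rec, config$average_window)
  avg <- baseline_subtract(avg, config$baseline_window)
  fwd <- build_forward(rec$depths, context = config$icsd_context,
                       sigma = config$sigma)
  csd <- delta_icsd(fwd, avg)
  interpolate_grid(crop_time(csd, config$analysis_window),
                   config$grid_M, config$grid_K)
}

# inhomogeneous-Poisson unit table sampled from simulated population rates
model_unit_table <- function(sim, n_units_per_pop = 40, n_trials = 10,
                             seed = NULL, animal_id = "model") {
  pops <- sim$network$populations
  units_l <- list(); spikes_l <- list()
  window_s <- range(sim$t) / 1000
  with_seed(seed, {
    for (i in seq_len(nrow(pops))) {
      nm <- pops$name[i]
      mode <- if (pops$sign[i] == "inhibitory") 0.25 else 0.55
      ids <- sprintf("%s_%s_u%03d", animal_id, nm, seq_len(n_units_per_pop))
      units_l[[i]] <- data.table::data.table(
        unit_id = ids, animal_id = animal_id, area = "V1",
        layer = pops$layer[i],
        duration_ms = pmax(0.1, rnorm(n_units_per_pop, mode, 0.05)),
        population = nm)
      rate <- sim$rates[nm, ]
      rfun <- function(t_ms) approx(sim$t, rate, xout = t_ms, rule = 2)$y
      trains <- sample_poisson_series(rfun, n_units_per_pop * n_trials,
                                      window_s)
      len <- lengths(trains)
      if (sum(len) > 0)
        spikes_l[[length(spikes_l) + 1L]] <- data.table::data.table(
          unit_id = rep(rep(ids, each = n_trials), len),
          trial = rep(rep(seq_len(n_trials), n_units_per_pop), len),
          spike_time_s = unlist(trains, use.names = FALSE))
    }
  })
  structure(list(units = data.table::rbindlist(units_l),
                 spikes = data.table::rbindlist(spikes_l),
                 n_trials = as.integer(n_trials), window_s = window_s),
            class = "unit_table")
}

#' Evaluate a model CSD pattern and spiking against a cohort
#'
#' Computes the total WD from the model pattern to the cohort's canonical
#' (PC 1) pattern and to the plain mean pattern, normalizes by the maximum
#' animal-to-PC1 distance, and assesses whether the model lies within the
#' cohort boxplot range. With model spiking supplied, adds per-population KS
#' similarities (baseline / peak / sustained) and rate correlations against
#' the pooled cohort, each with an outlier verdict against the cohort's
#' leave-one-out score distribution.
#'
#' @param model_pattern model [csd_pattern()] on the cohort analysis grid.
#' @param cohort cohort artifact list from [run_pipeline()] (fields
#'   `canonical`, `wd_to_pc1`, and optionally `units`, `loo_ks`,
#'   `loo_corr`).
#' @param model_units optional model `unit_table`.
#' @param windows a [window_set()].
#' @param sigma_bins rate smoothing.
#' @param exclude_animal optional cohort animal id to drop from the pooled
#'   reference (so evaluating a cohort member reproduces its leave-one-out
#'   scores).
#' @return Nested list (JSON-ready) of scores and verdicts.
#' @export
evaluate_model_against_cohort <- function(model_pattern, cohort,
                                          model_units = NULL,
                                          windows = window_set(),
                                          sigma_bins = 2,
                                          exclude_animal = NULL) {
  can <- cohort$canonical
  if (!same_grid(model_pattern, can$pc1))
    model_pattern <- regrid_to(model_pattern, can$pc1)
  wd_pc1 <- wd_csd(model_pattern, can$pc1)$wd_total
  wd_mean <- wd_csd(model_pattern, can$cohort_mean)$wd_total
  ref <- max(cohort$wd_to_pc1)
  out <- list(
    wd_to_pc1 = wd_pc1,
    wd_to_mean = wd_mean,
    wd_to_pc1_normalized = wd_pc1 / ref,
    wd_outlier = outlier_assessment(wd_pc1 / ref, cohort$wd_to_pc1 / ref))
  if (!is.null(model_units) && !is.null(cohort$units)) {
    cohort_units <- cohort$units
    if (!is.null(exclude_animal)) {
      keep <- cohort_units$units$animal_id != exclude_animal
      cohort_units <- structure(list(
        units = cohort_units$units[keep, ],
        spikes = cohort_units$spikes[
          cohort_units$spikes$unit_id %in% cohort_units$units$unit_id[keep], ],
        n_trials = cohort_units$n_trials,
        window_s = cohort_units$window_s), class = "unit_table")
    }
    units <- as.data.frame(cohort_units$units)
    units$pop <- population_labels(units)
    munits <- as.data.frame(model_units$units)
    munits$pop <- population_labels(munits)
    pops <- intersect(unique(munits$pop), unique(units$pop))
    spk <- list()
    for (pop in sort(pops)) {
      mine <- munits$unit_id[munits$pop == pop]
      ref_ids <- units$unit_id[units$pop == pop]
      kss <- lapply(windows, function(w)
        ks_similarity(window_mean_rates(model_units, w, mine),
                      window_mean_rates(cohort_units, w, ref_ids)))
      r <- tryCatch(rate_correlation(
        population_rate(model_units, mine, sigma_bins = sigma_bins),
        population_rate(cohort_units, ref_ids, sigma_bins = sigma_bins)),
        lamcsd_undefined_correlation = function(e) NA_real_)
      entry <- list(KSS_b = kss$baseline, KSS_p = kss$peak,
                    KSS_s = kss$sustained, r = r)
      if (!is.null(cohort$loo_ks)) {
        ck <- cohort$loo_ks[cohort$loo_ks$population == pop, ]
        if (nrow(ck) > 0)
          entry$ks_outliers <- list(
            baseline = outlier_assessment(entry$KSS_b, ck$KSS_b)$verdict,
            peak = outlier_assessment(entry$KSS_p, ck$KSS_p)$verdict,
            sustained = outlier_assessment(entry$KSS_s, ck$KSS_s)$verdict)
      }
      if (!is.null(cohort$loo_corr) && is.finite(r)) {
        cc <- cohort$loo_corr[cohort$loo_corr$population == pop, ]
        if (nrow(cc) > 0)
          entry$corr_outlier <- outlier_assessment(r, cc$r)$verdict
      }
      spk[[pop]] <- entry
    }
    out$spiking <- spk
  }
  out
}

#' Run the full analysis pipeline
#'
#' Generates a synthetic cohort, preprocesses each retained animal's LFP
#' (filter, downsample, trial-average, baseline-subtract), estimates CSD by
#' delta iCSD, regrids onto the common 30 x 100 analysis grid, extracts the
#' canonical pattern by PCA, computes pairwise and normalized Wasserstein
#' distances, generates and scores the spiking cohort, simulates the
#' laminar-model presets and evaluates them against the cohort, and writes
#' CSV/JSON artifacts plus a `summary.json` to the output directory. The run
#' is deterministic for a fixed config seed.
#'
#' @param config configuration list, see [default_config()].
#' @param stages subset of
#'   `c("cohort", "csd", "canonical", "wd", "spikes", "model")`; later
#'   stages require earlier ones within the same call.
#' @return Invisibly, a list with all in-memory artifacts and the summary.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("cohort", "csd", "canonical", "wd",
                                    "spikes", "model")) {
  config <- validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(config = config)
  res <- list(config = config)
  stage <- function(name) name %in% stages
  log_stage <- function(...) message(sprintf("[lamcsd] %s", sprintf(...)))

  manifest <- generate_cohort_manifest(
    config$n_animals, config$n_missing_lfp, config$n_bad_probe,
    config$n_no_units, config$n_trials, seed = config$seed)
  write_manifest(manifest, file.path(config$outdir, "manifest.csv"))
  csd_ids <- filter_cohort(manifest, "csd")
  spike_ids <- filter_cohort(manifest, "spikes")
  res$manifest <- manifest
  summary$cohort <- list(n_animals = nrow(manifest),
                         n_csd = length(csd_ids),
                         n_spikes = length(spike_ids))
  log_stage("cohort: %d animals, %d CSD-retained, %d spike-retained",
            nrow(manifest), length(csd_ids), length(spike_ids))

  if (stage("csd")) {
    log_stage("csd: preprocessing + delta iCSD for %d animals", length(csd_ids))
    pats <- list()
    for (an in csd_ids) {
      row <- manifest[manifest$animal_id == an, ]
      pats[[an]] <- animal_csd_pattern(config, row$seed)
    }
    res$patterns <- pats
  }

  if (stage("canonical") && !is.null(res$patterns)) {
    mat <- stack_cohort(res$patterns)
    res$stack <- mat
    res$canonical <- pca_canonical(mat)
    write.csv(data.frame(
      component = seq_along(res$canonical$explained_variance_ratio),
      explained_variance_ratio = res$canonical$explained_variance_ratio),
      file.path(config$outdir, "explained_variance.csv"), row.names = FALSE)
    write_grid_pattern(res$canonical$pc1, file.path(config$outdir, "pc1.json"))
    res$wd_to_pc1 <- vapply(res$patterns, function(p)
      wd_csd(p, res$canonical$pc1)$wd_total, 1.0)
    summary$canonical <- list(
      pc1_explained_variance = res$canonical$explained_variance_ratio[1],
      stack_dim = dim(mat))
    log_stage("canonical: PC1 explains %.1f%% of variance",
              100 * res$canonical$explained_variance_ratio[1])
  }

  if (stage("wd") && !is.null(res$patterns) && isTRUE(config$do_pairwise)) {
    log_stage("wd: pairwise distances over %d patterns", length(res$patterns))
    pw <- pairwise_wd(res$patterns)
    res$pairwise <- pw
    write.csv(pw$matrix, file.path(config$outdir, "wd_matrix.csv"))
    write.csv(pw$condensed, file.path(config$outdir, "wd_pairs.csv"),
              row.names = FALSE)
    summary$wd <- list(
      n_pairs = nrow(pw$condensed),
      max_pairwise = max(pw$condensed$wd),
      normalized_wd_to_pc1 =
        as.list(normalize_wd(res$wd_to_pc1, pw$condensed$wd)))
  }

  if (stage("spikes")) {
    log_stage("spikes: generating + scoring %d animals", length(spike_ids))
    specs <- default_population_rate_specs()
    if (config$spike_unit_scale != 1)
      specs <- lapply(specs, function(s) {
        s$n_units <- max(1L, as.integer(round(s$n_units *
                                                config$spike_unit_scale)))
        s
      })
    tabs <- lapply(spike_ids, function(an) {
      row <- manifest[manifest$animal_id == an, ]
      synth_spike_cohort(specs, config$n_trials,
                         seed = derive_seeds(row$seed, 3)[3], animal_id = an)
    })
    res$units <- bind_unit_tables(tabs)
    res$loo_ks <- leave_one_out_compare(res$units, "ks",
                                        min_cells = config$min_cells,
                                        sigma_bins = config$sigma_bins)
    res$loo_corr <- leave_one_out_compare(res$units, "corr",
                                          min_cells = config$min_cells,
                                          sigma_bins = config$sigma_bins)
    write.csv(res$loo_ks, file.path(config$outdir, "loo_ks.csv"),
              row.names = FALSE)
    write.csv(res$loo_corr, file.path(config$outdir, "loo_corr.csv"),
              row.names = FALSE)
    summary$spikes <- list(
      n_units = nrow(res$units$units),
      ks_median_by_population = lapply(
        split(res$loo_ks$KSS_p, res$loo_ks$population), median),
      corr_median_by_population = lapply(
        split(res$loo_corr$r, res$loo_corr$population),
        function(x) median(x, na.rm = TRUE)))
  }

  if (stage("model") && !is.null(res$canonical)) {
    evals <- list()
    for (preset in config$model_presets) {
      log_stage("model: preset '%s'", preset)
      net <- build_default_network(preset)
      sim <- simulate_network(net)
      pat <- interpolate_grid(crop_time(sim$csd_total, config$analysis_window),
                              config$grid_M, config$grid_K)
      munits <- model_unit_table(sim, config$model_units_per_pop,
                                 config$model_n_trials,
                                 seed = derive_seeds(config$seed, 10)[10])
      evals[[preset]] <- evaluate_model_against_cohort(
        pat, res, model_units = if (!is.null(res$units)) munits,
        sigma_bins = config$sigma_bins)
      evals[[preset]]$wd_outlier <- evals[[preset]]$wd_outlier[
        c("verdict", "whisker_low", "whisker_high")]
    }
    res$model_evaluations <- evals
    summary$model <- evals
  }

  summary_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary, summary_path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  res$summary <- summary
  log_stage("done: %s", summary_path)
  invisible(res)
}

#' Regenerate a machine-readable report (and figures) from saved artifacts
#'
#' Reads `summary.json` from a pipeline output directory, re-emits its
#' numbers as `report.json` (byte-stable for unchanged artifacts) and, when
#' the artifacts are present, renders a CSD heatmap of the canonical pattern
#' and a normalized-WD summary figure as PDFs.
#'
#' @param outdir pipeline output directory.
#' @param figures render PDF figures (default TRUE).
#' @return Invisibly, a list with the report and the paths written; missing
#'   artifacts are listed in `$missing`.
#' @export
make_report <- function(outdir, figures = TRUE) {
  missing <- character(0)
  spath <- file.path(outdir, "summary.json")
  if (!file.exists(spath))
    invalid_argument(sprintf("missing artifact: %s", spath))
  summary <- jsonlite::read_json(spath, simplifyVector = TRUE)
  report <- list(generated_from = "summary.json", sections = summary)
  for (f in c("pc1.json", "wd_pairs.csv", "loo_ks.csv"))
    if (!file.exists(file.path(outdir, f))) missing <- c(missing, f)
  report$missing <- missing
  rpath <- file.path(outdir, "report.json")
  jsonlite::write_json(report, rpath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  paths <- rpath
  if (figures && !("pc1.json" %in% missing)) {
    pc1 <- read_grid_pattern(file.path(outdir, "pc1.json"))
    fpath <- file.path(outdir, "fig_canonical_csd.pdf")
    grDevices::pdf(fpath, width = 5, height = 4)
    graphics::image(pc1$time_axis, pc1$depth_axis, t(pc1$values),
                    ylim = rev(range(pc1$depth_axis)),
                    xlab = "time (ms)", ylab = "depth (um)",
                    main = "canonical CSD pattern (PC 1)",
                    col = grDevices::hcl.colors(64, "RdBu"))
    grDevices::dev.off()
    paths <- c(paths, fpath)
  }
  if (figures && !("wd_pairs.csv" %in% missing)) {
    wd <- read.csv(file.path(outdir, "wd_pairs.csv"))
    fpath <- file.path(outdir, "fig_wd_distribution.pdf")
    grDevices::pdf(fpath, width = 4, height = 4)
    graphics::boxplot(wd$wd, ylab = "pairwise WD",
                      main = "inter-animal pattern distances")
    grDevices::dev.off()
    paths <- c(paths, fpath)
  }
  invisible(list(report = report, paths = paths, missing = missing))
}
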