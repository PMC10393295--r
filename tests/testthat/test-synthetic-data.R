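# Cohort manifests, ground-truth patterns, surrogate LFP, spike cohorts and
# the LGN input pool.

test_that("manifest carries the requested exclusion structure", {
  man <- generate_cohort_manifest(58, 5, 9, 2, 75, seed = 1)
  expect_equal(nrow(man), 58)
  expect_equal(sum(!man$has_v1_lfp), 5)
  expect_equal(sum(!man$probe_recoverable), 9)
  expect_equal(sum(!man$has_v1_units), 2)
  expect_false(anyDuplicated(man$animal_id) > 0)
  expect_true(all(man$n_trials == 75))
  # disjoint by default: no animal carries two flags
  flags <- (!man$has_v1_lfp) + (!man$probe_recoverable) + (!man$has_v1_units)
  expect_lte(max(flags), 1)
  # determinism
  expect_identical(man, generate_cohort_manifest(58, 5, 9, 2, 75, seed = 1))
  # no-flag case
  clean <- generate_cohort_manifest(10, 0, 0, 0, 1, seed = 2)
  expect_true(all(clean$has_v1_lfp & clean$probe_recoverable &
                    clean$has_v1_units))
})

test_that("manifest argument validation", {
  expect_error(generate_cohort_manifest(5, 6, 0, 0, 1, 1),
               class = "lamcsd_invalid_argument")
  expect_error(generate_cohort_manifest(10, 5, 5, 5, 1, 1),
               class = "lamcsd_invalid_argument")
  # overlap mode tolerates flag counts summing past n_animals
  man <- generate_cohort_manifest(10, 5, 5, 5, 1, 1, overlap = TRUE)
  expect_equal(sum(!man$has_v1_lfp), 5)
})

test_that("cohort filtering reproduces the retention arithmetic", {
  man <- generate_cohort_manifest(58, 5, 9, 2, 75, seed = 3)
  expect_length(filter_cohort(man, "csd"), 44)
  expect_length(filter_cohort(man, "spikes"), 47)
  expect_length(filter_cohort(man[0, ], "csd"), 0)
  clean <- generate_cohort_manifest(7, 0, 0, 0, 1, seed = 1)
  expect_equal(filter_cohort(clean, "csd"), clean$animal_id)
  # retained sets respect their flags and order
  csd_ids <- filter_cohort(man, "csd")
  sel <- man$animal_id %in% csd_ids
  expect_true(all(man$probe_recoverable[sel] & man$has_v1_lfp[sel]))
  expect_identical(csd_ids, man$animal_id[sel])
})

test_that("manifest round-trips through CSV", {
  man <- generate_cohort_manifest(12, 1, 2, 1, 5, seed = 9)
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  expect_equal(read_manifest(path), man)
})

dz <- seq(0, 860, by = 20)
tz <- seq(-50, 250, by = 2)

test_that("ground-truth pattern places the early sink in the L4 band", {
  truth <- synth_ground_truth_csd(canonical_components(), dz, tz)
  early <- truth$values[, tz < 50 & tz > 0]
  depth_at_min <- dz[which(early == min(early), arr.ind = TRUE)[1]]
  bnd <- layer_boundaries()
  expect_gte(depth_at_min, bnd[["4"]])
  expect_lt(depth_at_min, bnd[["5"]])
})

test_that("ground-truth pattern edge cases", {
  empty <- synth_ground_truth_csd(NULL, dz, tz)
  expect_true(all(empty$values == 0))
  p1 <- synth_ground_truth_csd(canonical_components(), dz, tz, jitter = NULL)
  p2 <- synth_ground_truth_csd(canonical_components(), dz, tz, jitter = NULL)
  expect_identical(p1$values, p2$values)
  # same seed, jittered -> identical; different seed -> different
  j <- variability_spec()
  a1 <- synth_ground_truth_csd(canonical_components(), dz, tz, j, seed = 5)
  a2 <- synth_ground_truth_csd(canonical_components(), dz, tz, j, seed = 5)
  a3 <- synth_ground_truth_csd(canonical_components(), dz, tz, j, seed = 6)
  expect_identical(a1$values, a2$values)
  expect_false(identical(a1$values, a3$values))
})

test_that("components outside the grid are clipped with a warning", {
  comp <- canonical_components()
  comp$depth_center[1] <- 2000
  expect_warning(synth_ground_truth_csd(comp, dz, tz), "clipped")
})

test_that("single-signed component support per polarity", {
  comp <- canonical_components()
  sink_only <- comp[comp$polarity == "sink", ]
  p <- synth_ground_truth_csd(sink_only, dz, tz)
  expect_lte(max(p$values), 0)
  src_only <- comp[comp$polarity == "source", ]
  p2 <- synth_ground_truth_csd(src_only, dz, tz)
  expect_gte(min(p2$values), 0)
})

test_that("surrogate LFP is forward-consistent", {
  comp <- canonical_components()
  truth <- synth_ground_truth_csd(comp, dz, tz)
  fwd <- build_forward(dz, context = "experiment")
  silent <- variability_spec(trial_noise_sd = 0, gamma_amplitude = 0)

  # zero truth, zero noise -> all-zero LFP
  zero <- synth_ground_truth_csd(NULL, dz, tz)
  rec0 <- synth_lfp_trials(zero, dz, 2, silent, fwd, seed = 1)
  expect_true(all(rec0$lfp == 0))

  # noiseless single trial: delta iCSD of the trial average recovers truth
  # (truth built on the sample-rate time grid so no resampling error enters)
  tz_fine <- seq(-300, 400, by = 0.8)          # 1250 Hz sample times
  truth_fine <- synth_ground_truth_csd(comp, dz, tz_fine)
  rec <- synth_lfp_trials(truth_fine, dz, 1, silent, fwd, seed = 1)
  avg <- trial_average(rec, window = c(0, 100))
  est <- delta_icsd(fwd, avg)
  ref <- synth_ground_truth_csd(comp, dz, avg$time_axis)
  expect_lt(max(abs(est$values - ref$values)) / max(abs(ref$values)), 1e-6)

  # averaging reduces the deviation from forward(truth)
  noisy <- variability_spec(trial_noise_sd = 0.003, gamma_amplitude = 0)
  rec1 <- synth_lfp_trials(truth_fine, dz, 1, noisy, fwd, seed = 2)
  rec75 <- synth_lfp_trials(truth_fine, dz, 75, noisy, fwd, seed = 2)
  clean <- trial_average(rec, window = c(0, 100))$values
  dev1 <- trial_average(rec1, window = c(0, 100))$values - clean
  dev75 <- trial_average(rec75, window = c(0, 100))$values - clean
  expect_lt(sqrt(mean(dev75^2)), sqrt(mean(dev1^2)))

  # mismatched electrode axes are rejected
  expect_error(synth_lfp_trials(truth, dz + 5, 1, silent, fwd),
               class = "lamcsd_invalid_argument")
})

test_that("spike cohorts have the requested rate structure", {
  specs <- list(
    population_rate_spec("RS L4", baseline_rate = 4, peak_rate = 20,
                         sustained_rate = 6, n_units = 150),
    population_rate_spec("FS", 0, 10, 3, n_units = 20,
                         waveform_duration_mode = 0.25))
  ut <- synth_spike_cohort(specs, n_trials = 30, seed = 11)
  # baseline-zero population emits no pre-stimulus spikes
  fs_ids <- ut$units$unit_id[ut$units$population == "FS"]
  fs_sp <- ut$spikes[ut$spikes$unit_id %in% fs_ids, ]
  expect_equal(sum(fs_sp$spike_time_s < 0), 0)
  # empirical baseline rate within 3 SE of the spec
  l4_ids <- ut$units$unit_id[ut$units$population == "RS L4"]
  rates <- window_mean_rates(ut, c(-250, 0), l4_ids)
  nobs <- length(l4_ids) * 30 * 0.25          # unit-trials x window (s)
  se <- sqrt(4 / nobs)
  expect_lt(abs(mean(rates) - 4), 3 * se)
  # determinism
  ut2 <- synth_spike_cohort(specs, n_trials = 30, seed = 11)
  expect_identical(ut$spikes, ut2$spikes)
  # validation
  expect_error(population_rate_spec("X", -1, 2, 1),
               class = "lamcsd_invalid_argument")
  expect_error(synth_spike_cohort(list(), 5),
               class = "lamcsd_invalid_argument")
})

test_that("waveform durations separate RS from FS at the 0.4 ms cutoff", {
  ut <- synth_spike_cohort(default_population_rate_specs(), 2, seed = 21)
  intended <- ifelse(ut$units$population == "FS", "FS", "RS")
  got <- classify_rs_fs(ut$units$duration_ms, ut$units$area)
  expect_gte(mean(got == intended), 0.95)
})

test_that("FS baseline exceeds twice every RS baseline in the defaults", {
  specs <- default_population_rate_specs()
  fs <- Filter(function(s) s$population == "FS", specs)[[1]]
  rs <- Filter(function(s) s$population != "FS", specs)
  for (s in rs) expect_gt(fs$baseline_rate, 2 * s$baseline_rate)
})

test_that("spike tables round-trip through the long CSV", {
  ut <- synth_spike_cohort(default_population_rate_specs()[1:2], 3, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_unit_table(ut, path)
  back <- read_unit_table(path, n_trials = 3)
  expect_setequal(back$units$unit_id, ut$units$unit_id)
  expect_equal(nrow(back$spikes), nrow(ut$spikes))
  expect_equal(sort(back$spikes$spike_time_s), sort(ut$spikes$spike_time_s))
})

test_that("LGN pool size is exactly units x recorded trials", {
  pool <- build_lgn_input_pool(40, 15, seed = 31)
  expect_length(pool$trains, 600)
  expect_equal(max(pool$unit), 40)
  expect_error(build_lgn_input_pool(0, 10),
               class = "lamcsd_invalid_argument")
})

test_that("train assignment covers every target unit in every trial", {
  pool <- build_lgn_input_pool(30, 10, seed = 32)
  asg <- assign_input_trains(pool, n_target_units = 200, n_sim_trials = 5,
                             n_subsets = 10, seed = 33)
  expect_equal(dim(asg), c(200, 5))
  expect_true(all(asg >= 1 & asg <= 300))
  # one subset per simulated trial
  subset_of <- attr(asg, "subset")
  for (j in 1:5) expect_true(all(subset_of[asg[, j]] == j))
  expect_error(assign_input_trains(pool, 10, 5, n_subsets = 3),
               class = "lamcsd_invalid_argument")
})

test_that("degenerate single-train pool feeds all targets", {
  pool <- build_lgn_input_pool(1, 1, seed = 35)
  asg <- assign_input_trains(pool, 3, 1, n_subsets = 1, seed = 36)
  expect_true(all(asg == 1))
})
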