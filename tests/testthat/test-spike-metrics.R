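# RS/FS classification, population rates, KS similarity, correlation,
# leave-one-out comparison, outlier assessment, unit-level moments.

test_that("RS/FS classification uses area-specific cutoffs with RS ties", {
  expect_equal(classify_rs_fs(0.55, "V1"), "RS")
  expect_equal(classify_rs_fs(0.25, "LGN"), "FS")
  expect_equal(classify_rs_fs(0.40, "V1"), "RS")     # boundary -> RS
  expect_equal(classify_rs_fs(0.30, "LGN"), "RS")    # boundary -> RS
  expect_equal(classify_rs_fs(0.35, "V1"), "FS")
  expect_equal(classify_rs_fs(0.35, "LM"), "FS")
  expect_equal(classify_rs_fs(0.35, "LGN"), "RS")
  expect_error(classify_rs_fs(0.3, "CA1"), class = "lamcsd_invalid_argument")
  expect_error(classify_rs_fs(-1, "V1"), class = "lamcsd_invalid_argument")
  # classification partitions every unit
  got <- classify_rs_fs(runif(50, 0.1, 0.9), "V1")
  expect_true(all(got %in% c("RS", "FS")))
})

make_ut <- function(rate = 10, n_units = 30, n_trials = 20, seed = 1) {
  synth_spike_cohort(list(population_rate_spec(
    "RS L4", rate, rate, rate, n_units = n_units)),
    n_trials = n_trials, seed = seed)
}

test_that("population rate recovers a homogeneous Poisson rate", {
  ut <- make_ut(rate = 10, n_units = 50, n_trials = 20, seed = 22)
  pr <- population_rate(ut, window = c(-250, 250))
  n_obs <- 50 * 20 * 0.5                    # unit-trials x seconds
  se <- sqrt(10 / n_obs)
  expect_lt(abs(mean(pr$rate) - 10), 3 * se)
  # integral preserved by smoothing (away from edge effects)
  expect_equal(mean(pr$rate), mean(pr$raw_rate), tolerance = 1e-2)
  # duplicated units leave the average unchanged
  ut2 <- ut
  dup <- ut$units; dup$unit_id <- paste0(dup$unit_id, "_b")
  spk <- ut$spikes; spk$unit_id <- paste0(spk$unit_id, "_b")
  ut2$units <- rbind(ut$units, dup); ut2$spikes <- rbind(ut$spikes, spk)
  pr2 <- population_rate(ut2, window = c(-250, 250))
  expect_equal(pr2$rate, pr$rate)
  # empty population errors; silent population is zero
  expect_error(population_rate(ut, character(0)),
               class = "lamcsd_invalid_argument")
  silent <- make_ut(rate = 0, n_units = 3, n_trials = 2)
  expect_true(all(population_rate(silent)$rate == 0))
})

test_that("ks_similarity spans [0, 1] with the documented anchors", {
  x <- rnorm(100)
  expect_equal(ks_similarity(x, x), 1)
  expect_equal(ks_similarity(x, x + 1000), 0)
  expect_equal(ks_similarity(x, x + 1000), ks_similarity(x + 1000, x))
  set.seed(23)
  u1 <- runif(4000); u2 <- runif(4000, 0.5, 1.5)
  expect_equal(ks_similarity(u1, u2), 0.5, tolerance = 0.05)
  expect_error(ks_similarity(numeric(0), x),
               class = "lamcsd_invalid_argument")
})

test_that("rate correlation behaves at its anchors and under the null", {
  t <- seq(-249.5, 249.5, by = 1)
  mk <- function(r) structure(list(t = t, rate = r), class = "population_rate")
  x <- pmax(sin(seq_along(t) / 9), 0) + 1
  expect_equal(rate_correlation(mk(x), mk(x)), 1)
  expect_equal(rate_correlation(mk(x), mk(max(x) - x)), -1)
  expect_error(rate_correlation(mk(x), mk(rep(1, length(t)))),
               class = "lamcsd_undefined_correlation")
  set.seed(24)
  null_r <- replicate(300, rate_correlation(mk(rnorm(length(t)) + 10),
                                            mk(rnorm(length(t)) + 10)))
  expect_gte(mean(abs(null_r) < 0.3), 0.97)
})

test_that("leave-one-out comparison scores identical animals perfectly", {
  specs <- list(population_rate_spec("RS L4", 3, 12, 5, n_units = 15))
  base <- synth_spike_cohort(specs, n_trials = 5, seed = 30, animal_id = "a1")
  clone <- base
  clone$units <- data.table::copy(base$units)
  clone$spikes <- data.table::copy(base$spikes)
  clone$units$animal_id <- "a2"
  clone$units$unit_id <- sub("^a1", "a2", clone$units$unit_id)
  clone$spikes$unit_id <- sub("^a1", "a2", clone$spikes$unit_id)
  ut <- bind_unit_tables(list(base, clone))
  ks <- leave_one_out_compare(ut, "ks")
  expect_true(all(abs(c(ks$KSS_b, ks$KSS_p, ks$KSS_s) - 1) < 1e-12))
  co <- leave_one_out_compare(ut, "corr")
  expect_true(all(abs(co$r - 1) < 1e-12))
})

test_that("populations under the cell criterion are skipped", {
  specs9 <- list(population_rate_spec("RS L4", 3, 10, 4, n_units = 9))
  specs12 <- list(population_rate_spec("RS L4", 3, 10, 4, n_units = 12))
  a <- synth_spike_cohort(specs9, 4, seed = 31, animal_id = "small")
  b <- synth_spike_cohort(specs12, 4, seed = 32, animal_id = "big1")
  cc <- synth_spike_cohort(specs12, 4, seed = 33, animal_id = "big2")
  ut <- bind_unit_tables(list(a, b, cc))
  ks <- leave_one_out_compare(ut, "ks", min_cells = 10)
  expect_false("small" %in% ks$animal)
  expect_setequal(ks$animal, c("big1", "big2"))
  skipped <- attr(ks, "skipped")
  expect_true("small" %in% skipped$animal)
  # results invariant to animal ordering
  ut_rev <- bind_unit_tables(list(cc, b, a))
  ks_rev <- leave_one_out_compare(ut_rev, "ks", min_cells = 10)
  ord <- order(ks$animal); ord_rev <- order(ks_rev$animal)
  expect_equal(ks[ord, c("KSS_b", "KSS_p", "KSS_s")],
               ks_rev[ord_rev, c("KSS_b", "KSS_p", "KSS_s")],
               ignore_attr = TRUE)
})

test_that("outlier assessment follows Tukey whiskers", {
  scores <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(outlier_assessment(median(scores), scores)$verdict, "within")
  expect_equal(outlier_assessment(100, scores)$verdict, "outlier")
  expect_equal(outlier_assessment(-100, scores)$verdict, "outlier")
  # degenerate box
  expect_equal(outlier_assessment(3, rep(3, 5))$verdict, "within")
  # a point beyond the whiskers but inside the raw range
  sc <- c(rep(5, 10), 30)
  oa <- outlier_assessment(29, sc)
  expect_equal(oa$verdict, "outlier")
  expect_equal(oa$verdict_raw, "within")
})

test_that("unit feature moments have the documented behaviour", {
  # two units with deterministic response peaks at 40 and 60 ms
  units <- data.table::data.table(
    unit_id = c("u1", "u2"), animal_id = c("a1", "a2"), area = "V1",
    layer = "4", duration_ms = 0.6, population = "RS L4")
  spikes <- data.table::data.table(
    unit_id = rep(c("u1", "u2"), each = 20),
    trial = rep(1:20, 2),
    spike_time_s = rep(c(0.0402, 0.0602), each = 20))
  ut <- structure(list(units = units, spikes = spikes, n_trials = 20L,
                       window_s = c(-0.1, 0.2)), class = "unit_table")
  mom <- unit_feature_moments(ut, "peak_latency")
  expect_equal(mom$mean, 50, tolerance = 1)
  # identical units -> zero SD, NaN higher moments, with a warning
  units2 <- data.table::data.table(
    unit_id = c("v1", "v2"), animal_id = c("a1", "a2"), area = "V1",
    layer = "4", duration_ms = 0.6, population = "RS L4")
  spikes2 <- data.table::data.table(
    unit_id = rep(c("v1", "v2"), each = 20),
    trial = rep(1:20, 2),
    spike_time_s = rep(0.0402, 40))
  both <- structure(list(units = units2, spikes = spikes2, n_trials = 20L,
                         window_s = c(-0.1, 0.2)), class = "unit_table")
  expect_warning(m2 <- unit_feature_moments(both, "peak_rate"), "NaN")
  expect_equal(m2$sd, 0)
  expect_true(is.nan(m2$skewness) && is.nan(m2$kurtosis_excess))
})

test_that("skewness of a symmetric feature distribution is near zero", {
  set.seed(43)
  x <- rnorm(1000)
  m <- mean(x); m2 <- mean((x - m)^2)
  expect_lt(abs(mean((x - m)^3) / m2^1.5), 0.1)
})
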