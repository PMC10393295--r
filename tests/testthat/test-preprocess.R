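# Channel selection, trial averaging, baseline subtraction, regridding.

make_rec <- function(nchan = 6, nsamp = 4000, fs = 1250, onsets = c(1, 2)) {
  laminar_recording(matrix(rnorm(nchan * nsamp), nchan),
                    depths = (seq_len(nchan) - 1) * 20, fs = fs,
                    trial_onsets = onsets)
}

test_that("select_channels keeps every other channel for 20 -> 40 um", {
  set.seed(1)
  rec <- make_rec(nchan = 8)
  out <- select_channels(rec, 40)
  # retention starts from the deepest channel (140 um), keeping every other
  expect_equal(out$depths, c(20, 60, 100, 140))
  expect_equal(out$lfp, rec$lfp[c(2, 4, 6, 8), ])
  expect_identical(select_channels(rec, 20)$lfp, rec$lfp)
  expect_error(select_channels(rec, 50), class = "lamcsd_invalid_argument")
  # monotone, uniform pitch preserved
  expect_true(all(diff(out$depths) == 40))
})

test_that("trial_average averages and re-references time", {
  fs <- 1000
  nsamp <- 3000
  x <- sin(2 * pi * 7 * seq_len(nsamp) / fs)
  rec <- laminar_recording(rbind(x, 2 * x), c(0, 20), fs,
                           trial_onsets = c(1.0, 2.0))
  # identical trials (periodic signal with integer-second onsets)
  avg <- trial_average(rec, c(-100, 100))
  expect_equal(avg$time_axis[1], -100)
  single <- rec$lfp[, 1001 + seq(-100, 100)]
  expect_equal(avg$values, single, ignore_attr = TRUE, tolerance = 1e-12)
  # cancellation
  rec2 <- laminar_recording(rbind(c(x, -x), c(x, -x)), c(0, 20), fs,
                            trial_onsets = c(1.0, 4.0))
  avg2 <- trial_average(rec2, c(-100, 100))
  expect_lt(max(abs(avg2$values)), 1e-12)
  # window bound violations name the trial
  expect_error(trial_average(rec, c(-2000, 100)), "trial")
})

test_that("averaging n trials shrinks iid noise like 1/sqrt(n)", {
  set.seed(2)
  fs <- 1000; n_trials <- 64; seg <- 400
  truth <- sin(2 * pi * 5 * seq_len(seg) / fs)
  lfp <- matrix(0, 2, seg * n_trials)
  for (k in seq_len(n_trials))
    lfp[, (k - 1) * seg + seq_len(seg)] <-
      rbind(truth, truth) + matrix(rnorm(2 * seg), 2)
  rec <- laminar_recording(lfp, c(0, 20), fs,
                           trial_onsets = ((seq_len(n_trials) - 1) * seg + 100) / fs)
  avg <- trial_average(rec, c(-50, 250))
  resid <- sweep(avg$values, 2, truth[100 + seq(-50, 250)])
  expect_equal(sd(resid), 1 / sqrt(n_trials), tolerance = 0.2)
})

test_that("baseline subtraction removes offsets and is idempotent", {
  p <- grid_pattern(matrix(rnorm(40), 4, 10) + c(1, -2, 5, 0),
                    seq(0, 60, by = 20), seq(-5, 4))
  b <- baseline_subtract(p, c(-5, 0))
  expect_equal(rowMeans(b$values[, p$time_axis < 0]), rep(0, 4))
  expect_equal(baseline_subtract(b, c(-5, 0))$values, b$values)
  # exact removal of constant offsets
  p2 <- grid_pattern(matrix(3, 4, 10), seq(0, 60, 20), seq(-5, 4))
  expect_true(all(baseline_subtract(p2, c(-5, 0))$values == 0))
  expect_error(baseline_subtract(p, c(-50, -40)),
               class = "lamcsd_invalid_argument")
})

test_that("bilinear regridding is exact on planes and idempotent", {
  z <- seq(0, 800, length.out = 9)
  t <- seq(0, 100, length.out = 21)
  plane <- outer(z, t, function(z, t) 0.3 * z - 1.7 * t + 4)
  p <- grid_pattern(plane, z, t)
  out <- interpolate_grid(p, 30, 100)
  ref <- outer(out$depth_axis, out$time_axis,
               function(z, t) 0.3 * z - 1.7 * t + 4)
  expect_equal(out$values, ref, tolerance = 1e-12)
  expect_equal(length(as.vector(out$values)), 3000)
  # endpoints preserved
  expect_equal(range(out$depth_axis), range(z))
  expect_equal(range(out$time_axis), range(t))
  # idempotent on its own grid
  again <- interpolate_grid(out, 30, 100)
  expect_equal(again$values, out$values, tolerance = 1e-12)
  expect_error(interpolate_grid(p, 1, 100), class = "lamcsd_invalid_argument")
})

test_that("filtering and trial averaging commute", {
  set.seed(3)
  rec <- make_rec(nchan = 3, nsamp = 6000, onsets = c(1, 2, 3))
  a <- trial_average(lowpass_filter(rec, 200), c(-100, 100))
  b_raw <- trial_average(rec, c(-100, 100))
  co <- butter_lowpass(5, 200, rec$fs)
  # filter the average directly (shorter segment -> same passband behaviour
  # away from edges)
  filt_avg <- t(apply(b_raw$values, 1, function(x) filtfilt(co$b, co$a, x)))
  core <- 60:190
  expect_equal(a$values[, core], filt_avg[, core], tolerance = 1e-2,
               ignore_attr = TRUE)
})

test_that("recordings round-trip through text serialization", {
  rec <- make_rec(nchan = 3, nsamp = 50)
  stem <- tempfile()
  write_recording(rec, stem)
  back <- read_recording(stem)
  expect_equal(back$lfp, rec$lfp, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$depths, rec$depths)
  expect_equal(back$fs, rec$fs)
})

test_that("grid patterns round-trip through JSON", {
  p <- make_pattern(matrix(rnorm(12), 3, 4))
  path <- tempfile(fileext = ".json")
  write_grid_pattern(p, path)
  back <- read_grid_pattern(path)
  expect_equal(back$values, p$values)
  expect_s3_class(back, "csd_pattern")
})
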