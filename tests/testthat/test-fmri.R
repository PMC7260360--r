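# Unit tests for the fMRI suppression pipeline.

test_that("voxel selection takes the top k and relaxes when few pass", {
  set.seed(8)
  p <- c(runif(30, 0, 1e-6), runif(70, 0.2, 1))  # 30 clearly significant
  sel <- select_voxels(p, k = 20)
  expect_length(sel, 20)
  expect_true(all(sel %in% order(p)[1:20]))
  expect_false(attr(sel, "relaxed"))

  p2 <- c(runif(5, 0, 1e-6), runif(95, 0.2, 1))  # only 5 pass corrected
  sel2 <- select_voxels(p2, k = 20)
  expect_length(sel2, 20)
  expect_true(attr(sel2, "relaxed"))

  expect_error(select_voxels(runif(10), k = 20), "fewer voxels")

  # two hemispheres give 2k voxels in total
  expect_length(c(select_voxels(p, 20), select_voxels(p2, 20)), 40)
})

test_that("epoching cuts 8-sample windows and drops edge events", {
  n_vol <- 125
  sig <- matrix(rep(seq_len(n_vol), each = 3), nrow = 3)
  ts <- roi_timeseries(sig, tr = 2, event_times = c(2, 50, 100, 240))
  ep <- extract_epochs(ts)
  # events at 2 s (needs 4 s pre) and 240 s (needs 12 s post) are dropped
  expect_equal(nrow(ep$epochs), 2)
  expect_equal(ep$n_dropped, 2)
  expect_equal(ncol(ep$epochs), 8)
  expect_equal(ep$times, seq(-4, 10, by = 2))

  const <- roi_timeseries(matrix(7, 2, 60), tr = 2, event_times = c(40, 60))
  epc <- extract_epochs(const)
  expect_true(all(epc$epochs == 7))

  expect_error(extract_epochs(
    roi_timeseries(matrix(1, 2, 10), tr = 2, event_times = 2)), "usable")
})

test_that("percent signal change zeroes the pooled baseline and ignores scanner gain", {
  set.seed(9)
  sig <- matrix(100 + rnorm(2 * 125), 2, 125)
  ts <- roi_timeseries(sig, tr = 2, event_times = c(30, 50, 70))
  psc <- percent_signal_change(extract_epochs(ts))
  base_cols <- psc$times >= -4 & psc$times < 0
  expect_equal(mean(psc$epochs[, base_cols]), 0, tolerance = 1e-12)

  # x == b everywhere -> PSC == 0; b = 100, x = 99 -> -1%
  flat <- roi_timeseries(matrix(100, 2, 60), 2, c(30, 40))
  expect_true(all(percent_signal_change(extract_epochs(flat))$epochs == 0))
  expect_equal(100 * (99 - 100) / 100, -1)

  # global multiplicative scaling leaves PSC unchanged
  ts2 <- roi_timeseries(sig * 3.7, tr = 2, event_times = c(30, 50, 70))
  psc2 <- percent_signal_change(extract_epochs(ts2))
  expect_equal(psc2$epochs, psc$epochs, tolerance = 1e-12)
})

test_that("suppression magnitude averages the 8-12 s window", {
  ep <- structure(list(epochs = matrix(-0.5, 5, 8),
                       times = seq(-4, 10, by = 2), units = "percent",
                       n_dropped = 0), class = "epoch_set")
  expect_equal(suppression_magnitude(ep), -0.5)

  # epochs-then-window equals window-then-epochs (linearity of the mean)
  set.seed(10)
  ep$epochs <- matrix(rnorm(40), 5, 8)
  win <- ep$times >= 8 & ep$times < 12
  expect_equal(suppression_magnitude(ep),
               mean(rowMeans(ep$epochs[, win])))
  expect_equal(suppression_magnitude(ep),
               mean(colMeans(ep$epochs[, win])))
})

test_that("framewise displacement follows the rigid-body convention", {
  zero <- matrix(0, 10, 6)
  fd0 <- framewise_displacement(zero)
  expect_true(all(fd0$fd == 0))

  m <- matrix(0, 5, 6)
  m[3:5, 1] <- 1           # single 1 mm x-translation step at volume 3
  fd <- framewise_displacement(m)
  expect_equal(fd$fd[3], 1)
  expect_equal(sum(fd$fd), 1)

  r <- matrix(0, 4, 6)
  r[2:4, 5] <- 0.01        # 0.01 rad rotation step -> 0.5 mm on 50 mm sphere
  expect_equal(framewise_displacement(r)$fd[2], 0.5)
})

test_that("noise-only runs carry no systematic suppression", {
  cfg <- bold_config(n_voxels = 8)
  set.seed(12)
  vals <- vapply(seq_len(1000), function(i)
    analyze_fmri_runs(list(generate_bold(0, cfg))), numeric(1))
  sem <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * sem)
})

test_that("synthetic BOLD matches the block-design geometry", {
  set.seed(13)
  b <- generate_bold(-0.5, bold_config(n_voxels = 4))
  expect_equal(ncol(b$signal), 125)              # 250 s at TR 2 s
  expect_length(b$event_times, 12)               # one per larger block
  expect_equal(b$event_times[1], 10)
  # noiseless run inverts exactly through the analysis pipeline
  quiet <- generate_bold(-0.5, bold_config(n_voxels = 2, noise_sd = 0))
  expect_equal(analyze_fmri_runs(list(quiet)), -0.5, tolerance = 1e-6)
})
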