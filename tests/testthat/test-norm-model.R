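# Unit tests for the divisive-normalization model components.

test_that("excitatory drive is zero at zero contrast and linear in contrast", {
  p <- coarse_params()
  E0 <- stimulus_drive(stimulus_spec(1.7, 0), p)
  expect_true(all(E0$values == 0))

  E1 <- stimulus_drive(stimulus_spec(1.7, 0.03), p)
  E2 <- stimulus_drive(stimulus_spec(1.7, 0.06), p)
  expect_equal(E2$values, 2 * E1$values, tolerance = 1e-12)
  expect_true(all(E1$values >= 0))
})

test_that("a larger stimulus drives a larger spatial integral of E", {
  p <- coarse_params()
  int_for <- function(d) {
    E <- stimulus_drive(stimulus_spec(d, 0.5), p)
    sum(E$values) * p$grid_step
  }
  expect_gt(int_for(10), int_for(1.7))
  expect_gt(int_for(1.7), int_for(0.84))
})

test_that("top-down field has unit baseline, peak m_gain, and narrow fields carry less gain", {
  p <- coarse_params(m_gain = 1)
  M <- topdown_field(p)
  expect_true(all(M$values == 1))

  p2 <- coarse_params(m_gain = 3, m_width = 14)
  M2 <- topdown_field(p2)
  expect_true(all(M2$values >= 1))
  expect_equal(max(M2$values), 3, tolerance = 1e-6)
  # grid extent (15 deg) far exceeds 6 * m_width (0.84 deg): edge gain ~ 1
  expect_lt(max(M2$values[1, ]) - 1, 1e-6)

  gain_integral <- function(w) {
    M <- topdown_field(coarse_params(m_gain = 3, m_width = w))
    sum(M$values[, 1] - 1) * p$grid_step
  }
  expect_lt(gain_integral(6), gain_integral(14))
})

test_that("suppressive drive pools and broadens the modulated excitation", {
  p <- coarse_params()
  g0 <- stimulus_drive(stimulus_spec(1.7, 0), p)
  expect_true(all(suppressive_drive(g0, p)$values == 0))

  # Gaussian convolution adds the pool variance to the field variance
  E <- stimulus_drive(stimulus_spec(1.7, 0.5), p)
  S <- suppressive_drive(E, p)
  svar <- function(f) {
    w <- f$values[, which.min(abs(f$theta))]
    x <- f$x
    m <- sum(x * w) / sum(w)
    sum((x - m)^2 * w) / sum(w)
  }
  expect_equal(svar(S) - svar(E), p$x_w_s^2, tolerance = 0.02 * p$x_w_s^2)
})

test_that("broader top-down gain engages the suppressive pool more for large stimuli", {
  s_center <- function(m_width) {
    p <- norm_model_params(m_width = m_width)
    R <- model_response(stimulus_spec(10, 0.98), p)
    S <- attr(R, "S")
    S$values[which.min(abs(S$x)), which.min(abs(S$theta))]
  }
  expect_gt(s_center(14), s_center(6))
})

test_that("model response is finite, non-negative, and contrast-monotone at the peak", {
  p <- coarse_params()
  R0 <- model_response(stimulus_spec(1.7, 0), p)
  expect_true(all(R0$values == 0))
  for (d in c(0.84, 1.7, 10)) {
    r_lo <- readout_peak(model_response(stimulus_spec(d, 0.03), p), p)
    r_hi <- readout_peak(model_response(stimulus_spec(d, 0.98), p), p)
    expect_gt(r_hi, r_lo)
    expect_true(is.finite(r_hi) && r_hi > 0)
  }
})

test_that("readout averages the window and never gains from widening over a peak", {
  p <- coarse_params()
  g <- spatsupp:::field_grid(p)
  const <- spatsupp:::neural_field(
    matrix(2.5, length(g$x), length(g$theta)), g$x, g$theta)
  expect_equal(readout_peak(const, p), 2.5)

  R <- model_response(stimulus_spec(0.84, 0.98), p)
  widths <- c(4, 6, 20, 60)
  vals <- vapply(widths, function(w) {
    pw <- coarse_params(readout_width = w)
    readout_peak(R, pw)
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("threshold readout follows T = C / R_peak", {
  p <- coarse_params()
  stim <- stimulus_spec(1.7, 0.98)
  rp <- readout_peak(model_response(stim, p), p)
  p_unit <- coarse_params(C = rp)
  expect_equal(predict_threshold(stim, p_unit), 1, tolerance = 1e-10)

  t1 <- predict_threshold(stim, coarse_params(C = 1))
  t2 <- predict_threshold(stim, coarse_params(C = 2))
  expect_equal(t2, 2 * t1, tolerance = 1e-12)

  expect_error(predict_threshold(stimulus_spec(1.7, 0), p), "unresolvable")
})

test_that("threshold surface is complete, positive and deterministic", {
  p <- coarse_params()
  s1 <- threshold_surface(p)
  expect_equal(nrow(s1), 6)
  expect_true(all(s1$threshold > 0))
  expect_identical(s1, threshold_surface(p))
})

test_that("variants perturb exactly the specified parameter", {
  p <- norm_model_params()
  expect_equal(unclass(apply_variant(p, "baseline_nt")), unclass(p))
  expect_equal(apply_variant(p, "weaker_normalization")$S_g, 0.75)
  expect_equal(apply_variant(p, "larger_sf")$x_w_e, p$x_w_e * 1.25)
  expect_equal(apply_variant(p, "narrow_topdown")$m_width, 6)
  expect_equal(apply_variant(p, "extra_narrow_topdown")$m_width, 2)
  expect_equal(
    apply_variant(p, "extra_narrow_topdown", extra_narrow_width = 1)$m_width,
    1)
  expect_error(apply_variant(p, "no_such_variant"))
  # input untouched
  apply_variant(p, "weaker_normalization")
  expect_equal(p$S_g, 1)
})

test_that("configuration errors are caught", {
  p <- norm_model_params(grid_extent = 4)
  expect_error(stimulus_drive(stimulus_spec(10, 0.5), p), "grid")
  expect_error(norm_model_params(x_w_s = 0.2), "x_w_s")
  expect_error(norm_model_params(sigma = 0))
})

test_that("model parameters round-trip through JSON", {
  p <- norm_model_params(m_width = 6, sigma = 0.02)
  f <- tempfile(fileext = ".json")
  write_model_params(p, f)
  expect_equal(unclass(read_model_params(f)), unclass(p))
  unlink(f)
})
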