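# Unit tests for the staircase task simulator and psychometric fitting.

test_that("observer accuracy spans the guess floor, lapse ceiling and 80% at threshold", {
  obs <- observer_spec(data.frame(size_deg = 1.7, contrast = 0.98,
                                  threshold_ms = 100))
  set.seed(1)
  acc_at <- function(dur, n = 10000)
    mean(vapply(seq_len(n), function(i)
      observer_response(obs, 1.7, 0.98, dur), logical(1)))
  expect_equal(acc_at(1e-4, 8000), 0.5, tolerance = 0.035)
  expect_equal(acc_at(1e5, 4000), 0.96, tolerance = 0.02)
  expect_equal(acc_at(100, 10000), 0.80, tolerance = 0.0125)
})

test_that("Psi staircase tracks the observer and is reproducible", {
  obs <- six_condition_observer()
  cfg <- staircase_config()

  set.seed(5)
  a <- psi_staircase(obs, 1.7, 0.98, cfg)
  set.seed(5)
  b <- psi_staircase(obs, 1.7, 0.98, cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 30)
  expect_true(all(a$duration_ms >= 6.7 & a$duration_ms <= 333))

  up <- psi_staircase(obs, 1.7, 0.98, cfg, respond = function(d) TRUE)
  expect_lt(up$duration_ms[30], up$duration_ms[1])
  down <- psi_staircase(obs, 1.7, 0.98, cfg, respond = function(d) FALSE)
  expect_gt(down$duration_ms[30], down$duration_ms[1])
  expect_equal(down$duration_ms[30], 333, tolerance = 1e-6)
})

test_that("Weibull fit matches the closed-form threshold inversion", {
  # threshold80 = alpha * u^(1/beta), u = -log(1 - 0.3/0.46)
  u <- -log(1 - (0.8 - 0.5) / (1 - 0.5 - 0.04))
  expect_equal(u, 1.056053, tolerance = 1e-6)
  expect_equal(threshold_from_alpha(120, 3), 120 * u^(1 / 3))
  expect_equal(alpha_from_threshold(threshold_from_alpha(77, 2.2), 2.2), 77)

  set.seed(11)
  tr <- weibull_trials(alpha = 100, beta = 3, n_per_level = 40)
  f <- fit_weibull(tr$duration_ms, tr$correct)
  expect_true(f$converged)
  expect_equal(f$threshold80,
               threshold_from_alpha(f$alpha, f$beta), tolerance = 1e-9)

  # duplicating every trial rescales the likelihood but not its argmax
  f2 <- fit_weibull(rep(tr$duration_ms, 2), rep(tr$correct, 2))
  expect_equal(f2$threshold80, f$threshold80, tolerance = 1e-4)
})

test_that("fit recovers a known observer from a session-sized trial set", {
  # 480 Psi-placed trials (a full session's worth on one condition):
  # threshold80 recovered within 10% in at least 95% of replicates
  truth <- threshold_from_alpha(100, 3)
  obs16 <- data.frame(participant = sprintf("S%02d", 1:16), group = "NT",
                      size_deg = 1.7, contrast = 0.98,
                      threshold_ms = truth)
  cfg1 <- staircase_config(n_runs = 1, catch_trials_per_run = 0)
  set.seed(77)
  ok <- vapply(seq_len(200), function(i) {
    tr <- simulate_behavior(obs16, cfg1)
    tr <- tr[!tr$is_catch, ]
    f <- fit_weibull(tr$duration_ms, tr$correct)
    abs(f$threshold80 - truth) / truth < 0.10
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("degenerate trial data is flagged unconverged", {
  f <- fit_weibull(c(100, 100, 100), c(TRUE, FALSE, TRUE))
  expect_false(f$converged)
  expect_true(is.na(f$threshold80))
  f2 <- fit_weibull(c(50, 100, 200), c(TRUE, TRUE, TRUE))
  expect_false(f2$converged)
})

test_that("exclusion rules apply the documented boundaries", {
  thr <- data.frame(participant = c("A", "A", "B", "C"),
                    threshold_ms = c(120, 501, 80, 90))
  catch <- function(id, n_correct)
    data.frame(participant = id, group = "NT", run = 1, size_deg = 10,
               contrast = 0.98, is_catch = TRUE, trial = 1:40,
               duration_ms = 333,
               correct = c(rep(TRUE, n_correct), rep(FALSE, 40 - n_correct)))
  trials <- rbind(catch("A", 40), catch("B", 32), catch("C", 31))
  res <- apply_exclusions(thr, trials)
  # threshold > 500 ms dropped
  expect_equal(res$n_thresholds_dropped, 1)
  # exactly 80% catch accuracy is retained, 77.5% is excluded
  expect_true("B" %in% res$thresholds$participant)
  expect_identical(res$excluded_participants, "C")
  expect_false("C" %in% res$thresholds$participant)
})

test_that("size index follows the log-ratio definition and ignores units", {
  thr <- data.frame(size_deg = c(1.7, 10), contrast = 0.98,
                    threshold_ms = c(50, 200))
  expect_equal(size_index(thr, 0.98), log10(50) - log10(200))
  expect_equal(size_index(thr, 0.98), -0.602, tolerance = 1e-3)
  thr_s <- thr
  thr_s$threshold_ms <- thr_s$threshold_ms / 1000
  expect_equal(size_index(thr_s, 0.98), size_index(thr, 0.98))
  thr_eq <- data.frame(size_deg = c(1.7, 10), contrast = 0.98,
                       threshold_ms = c(120, 120))
  expect_equal(size_index(thr_eq, 0.98), 0)
  expect_true(is.na(size_index(thr, 0.03)))
})

test_that("cohort simulation produces the protocol's trial counts", {
  obs <- data.frame(participant = rep(c("P1", "P2"), each = 6),
                    group = "NT",
                    size_deg = rep(c(0.84, 1.7, 10), 4),
                    contrast = rep(c(0.03, 0.98), each = 3),
                    threshold_ms = 100)
  tr <- simulate_behavior(obs, seed = 3)
  # 2 participants x (6 staircases x 4 runs x 30 trials + 4 x 10 catch)
  expect_equal(nrow(tr), 2 * (6 * 4 * 30 + 40))
  expect_equal(sum(tr$is_catch), 80)
  expect_true(all(tr$duration_ms[tr$is_catch] == 333))
  tr2 <- simulate_behavior(obs, seed = 3)
  expect_identical(tr, tr2)
})
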