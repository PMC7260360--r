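# Motion duration-threshold psychophysics: Weibull observers, the adaptive
# (Psi) staircase, maximum-likelihood psychometric fitting, exclusion rules
# and the size index.

#' Weibull psychometric function
#'
#' Probability of a correct left/right motion judgement at a given stimulus
#' duration, for a Weibull observer with guess rate `gamma` and lapse rate
#' `lambda`:
#' `p = gamma + (1 - gamma - lambda) * (1 - exp(-(x / alpha)^beta))`.
#'
#' @param duration Stimulus duration (ms), vectorized.
#' @param alpha Weibull scale (ms).
#' @param beta Weibull slope.
#' @param gamma Guess rate (default 0.5, two-alternative task).
#' @param lambda Lapse rate (default 0.04).
#' @return Probability of a correct response.
#' @export
weibull_p <- function(duration, alpha, beta, gamma = 0.5, lambda = 0.04) {
  gamma + (1 - gamma - lambda) * (1 - exp(-(duration / alpha)^beta))
}

# scale factor u such that threshold80 = alpha * u^(1/beta)
weibull_u <- function(crit = 0.8, gamma = 0.5, lambda = 0.04) {
  -log(1 - (crit - gamma) / (1 - gamma - lambda))
}

#' Convert between Weibull scale and the 80%-correct threshold
#'
#' Closed-form inversion of the Weibull psychometric function at the
#' criterion performance level (default 80% correct).
#'
#' @param threshold80 Duration at criterion accuracy (ms).
#' @param alpha Weibull scale (ms).
#' @inheritParams weibull_p
#' @param crit Criterion accuracy (default 0.8).
#' @return The corresponding `alpha` or `threshold80`.
#' @export
alpha_from_threshold <- function(threshold80, beta, gamma = 0.5,
                                 lambda = 0.04, crit = 0.8) {
  threshold80 / weibull_u(crit, gamma, lambda)^(1 / beta)
}

#' @rdname alpha_from_threshold
#' @export
threshold_from_alpha <- function(alpha, beta, gamma = 0.5, lambda = 0.04,
                                 crit = 0.8) {
  alpha * weibull_u(crit, gamma, lambda)^(1 / beta)
}

#' Synthetic Weibull observer
#'
#' Describes a simulated participant by their true 80%-correct duration
#' threshold in each condition, a common psychometric slope, fixed guess and
#' lapse rates, and an off-task (catch-trial) accuracy.
#'
#' @param thresholds Data frame with columns `size_deg`, `contrast`,
#'   `threshold_ms` (> 0), one row per condition.
#' @param beta Weibull slope shared across conditions (default 3).
#' @param gamma,lambda Guess and lapse rates (fixed at 0.5 and 0.04).
#' @param catch_accuracy Probability correct on catch trials.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(thresholds, beta = 3, gamma = 0.5, lambda = 0.04,
                          catch_accuracy = 0.97) {
  stopifnot(is.data.frame(thresholds),
            all(c("size_deg", "contrast", "threshold_ms") %in%
                  names(thresholds)),
            all(thresholds$threshold_ms > 0),
            beta > 0, gamma + lambda < 1,
            catch_accuracy >= 0, catch_accuracy <= 1)
  structure(list(thresholds = thresholds, beta = beta, gamma = gamma,
                 lambda = lambda, catch_accuracy = catch_accuracy),
            class = "observer_spec")
}

observer_alpha <- function(obs, size_deg, contrast) {
  i <- which(obs$thresholds$size_deg == size_deg &
               obs$thresholds$contrast == contrast)
  if (length(i) != 1) stop("condition not found in observer spec")
  alpha_from_threshold(obs$thresholds$threshold_ms[i], obs$beta,
                       obs$gamma, obs$lambda)
}

#' Simulate a single observer response
#'
#' Bernoulli draw from the observer's Weibull psychometric function at the
#' given duration. Uses R's RNG; seed with [set.seed()] for reproducibility.
#'
#' @param obs An [observer_spec()].
#' @param size_deg,contrast Condition identifiers.
#' @param duration Stimulus duration (ms, > 0).
#' @return Logical: correct response.
#' @export
observer_response <- function(obs, size_deg, contrast, duration) {
  stopifnot(duration > 0)
  a <- observer_alpha(obs, size_deg, contrast)
  stats::runif(1) < weibull_p(duration, a, obs$beta, obs$gamma, obs$lambda)
}

#' Staircase configuration
#'
#' Settings of the adaptive (Psi) staircase protocol: 30 trials per
#' staircase, 6 interleaved staircases per run (3 sizes x 2 contrasts), 4
#' runs, 10 catch trials per run at 333 ms, stimulus durations restricted to
#' 6.7-333 ms. The Psi procedure maintains a posterior over a log-spaced
#' (alpha, beta) grid with a uniform prior and proposes, on every trial, the
#' duration (from a log-spaced candidate grid) minimizing the expected
#' posterior entropy.
#'
#' @param n_trials Trials per staircase.
#' @param n_runs Runs per session.
#' @param catch_trials_per_run Catch trials per run.
#' @param duration_range Allowed durations (ms), `c(min, max)`.
#' @param catch_duration_ms Duration of catch trials (ms).
#' @param sizes,contrasts Condition levels (one staircase per combination
#'   per run).
#' @param alpha_grid,beta_grid Psi posterior grids.
#' @param duration_grid Candidate stimulus durations (ms), clamped to
#'   `duration_range`.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(n_trials = 30, n_runs = 4,
                             catch_trials_per_run = 10,
                             duration_range = c(6.7, 333),
                             catch_duration_ms = 333,
                             sizes = c(0.84, 1.7, 10),
                             contrasts = c(0.03, 0.98),
                             alpha_grid = exp(seq(log(5), log(500),
                                                  length.out = 31)),
                             beta_grid = exp(seq(log(0.5), log(8),
                                                 length.out = 9)),
                             duration_grid = exp(seq(log(6.7), log(333),
                                                     length.out = 20))) {
  stopifnot(n_trials >= 1, n_runs >= 1, duration_range[1] > 0,
            duration_range[2] > duration_range[1])
  duration_grid <- pmin(pmax(duration_grid, duration_range[1]),
                        duration_range[2])
  structure(list(n_trials = n_trials, n_runs = n_runs,
                 catch_trials_per_run = catch_trials_per_run,
                 duration_range = duration_range,
                 catch_duration_ms = catch_duration_ms,
                 sizes = sizes, contrasts = contrasts,
                 alpha_grid = alpha_grid, beta_grid = beta_grid,
                 duration_grid = duration_grid),
            class = "staircase_config")
}

# Batch Psi engine. Runs `n` independent staircases simultaneously, one
# posterior per row, using BLAS matrix products for the expected-entropy
# minimization. `respond(durations, stair_index)` returns the logical
# response vector; the default draws from each staircase's true Weibull.
psi_engine <- function(alpha_true, beta_true, gamma, lambda, cfg,
                       respond = NULL) {
  n <- length(alpha_true)
  stopifnot(length(beta_true) %in% c(1, n))
  if (length(beta_true) == 1) beta_true <- rep(beta_true, n)
  ab <- expand.grid(alpha = cfg$alpha_grid, beta = cfg$beta_grid,
                    KEEP.OUT.ATTRS = FALSE)
  d <- cfg$duration_grid
  # P[k, cell]: p(correct | duration k, psychometric cell)
  P <- outer(seq_along(d), seq_len(nrow(ab)), function(k, j)
    weibull_p(d[k], ab$alpha[j], ab$beta[j], gamma, lambda))
  Q <- 1 - P
  tP <- t(P); tQ <- t(Q)
  tPlogP <- t(P * log(P)); tQlogQ <- t(Q * log(Q))
  post <- matrix(1 / nrow(ab), nrow = n, ncol = nrow(ab))
  dur_out <- matrix(NA_real_, n, cfg$n_trials)
  cor_out <- matrix(NA, n, cfg$n_trials)
  for (t in seq_len(cfg$n_trials)) {
    lp <- log(post)
    ph <- post %*% tP                      # n x D  P(correct | history)
    hs <- -((post * lp) %*% tP + post %*% tPlogP) / ph + log(ph)
    pf <- 1 - ph
    hf <- -((post * lp) %*% tQ + post %*% tQlogQ) / pf + log(pf)
    eh <- ph * hs + pf * hf                # expected posterior entropy
    pick <- max.col(-eh, ties.method = "first")
    dur <- d[pick]
    if (is.null(respond)) {
      p_true <- weibull_p(dur, alpha_true, beta_true, gamma, lambda)
      resp <- stats::runif(n) < p_true
    } else {
      resp <- respond(dur, seq_len(n))
    }
    like <- P[pick, , drop = FALSE]
    like[!resp, ] <- Q[pick[!resp], , drop = FALSE]
    post <- post * like
    post <- post / rowSums(post)
    dur_out[, t] <- dur
    cor_out[, t] <- resp
  }
  list(duration_ms = dur_out, correct = cor_out)
}

#' Run one adaptive (Psi) staircase
#'
#' Simulates a 30-trial Psi staircase for one observer and condition. Each
#' trial's duration minimizes the expected posterior entropy over the
#' (alpha, beta) grid given the trial history, clamped to the allowed
#' duration range. Reproducible under [set.seed()].
#'
#' @inheritParams observer_response
#' @param cfg A [staircase_config()].
#' @param respond Optional deterministic response function
#'   `function(duration) logical(1)`; replaces the stochastic observer
#'   (used for testing staircase dynamics).
#' @return A data frame of trials: `trial`, `size_deg`, `contrast`,
#'   `duration_ms`, `correct`.
#' @export
psi_staircase <- function(obs, size_deg, contrast,
                          cfg = staircase_config(), respond = NULL) {
  a <- observer_alpha(obs, size_deg, contrast)
  rfun <- if (is.null(respond)) NULL else
    function(dur, idx) vapply(dur, respond, logical(1))
  out <- psi_engine(a, obs$beta, obs$gamma, obs$lambda, cfg, rfun)
  data.frame(trial = seq_len(cfg$n_trials), size_deg = size_deg,
             contrast = contrast, duration_ms = out$duration_ms[1, ],
             correct = out$correct[1, ])
}

#' Simulate the full behavioral session for a cohort
#'
#' Runs the complete duration-threshold protocol -- `n_runs` runs of 6
#' interleaved Psi staircases (3 sizes x 2 contrasts) plus catch trials --
#' for every observer. All staircases are advanced in a single vectorized
#' Psi engine, so cohort-scale simulation is fast.
#'
#' @param observers Data frame with one row per participant x condition:
#'   `participant`, `group`, `size_deg`, `contrast`, `threshold_ms`, and
#'   optionally `beta`, `catch_accuracy`.
#' @param cfg A [staircase_config()].
#' @param seed Optional integer seed.
#' @return A tidy trial table: `participant`, `group`, `run`, `size_deg`,
#'   `contrast`, `is_catch`, `trial`, `duration_ms`, `correct`.
#' @export
simulate_behavior <- function(observers, cfg = staircase_config(),
                              seed = NULL) {
  stopifnot(all(c("participant", "group", "size_deg", "contrast",
                  "threshold_ms") %in% names(observers)))
  if (!is.null(seed)) set.seed(seed)
  beta <- if ("beta" %in% names(observers)) observers$beta else 3
  catch_acc <- if ("catch_accuracy" %in% names(observers))
    observers$catch_accuracy else 0.97
  # one staircase per observer-condition row per run
  idx <- rep(seq_len(nrow(observers)), times = cfg$n_runs)
  run <- rep(seq_len(cfg$n_runs), each = nrow(observers))
  alpha <- alpha_from_threshold(observers$threshold_ms[idx],
                                if (length(beta) == 1) beta else beta[idx])
  out <- psi_engine(alpha, if (length(beta) == 1) beta else beta[idx],
                    0.5, 0.04, cfg)
  n_stair <- length(idx)
  trials <- data.frame(
    participant = rep(observers$participant[idx], each = cfg$n_trials),
    group = rep(observers$group[idx], each = cfg$n_trials),
    run = rep(run, each = cfg$n_trials),
    size_deg = rep(observers$size_deg[idx], each = cfg$n_trials),
    contrast = rep(observers$contrast[idx], each = cfg$n_trials),
    is_catch = FALSE,
    trial = rep(seq_len(cfg$n_trials), times = n_stair),
    duration_ms = as.vector(t(out$duration_ms)),
    correct = as.vector(t(out$correct)))
  # catch trials: per participant per run, at the fixed catch duration
  pp <- unique(observers[, c("participant", "group")])
  acc <- if (length(catch_acc) == 1) rep(catch_acc, nrow(observers)) else
    catch_acc
  acc_pp <- acc[match(pp$participant, observers$participant)]
  nc <- cfg$catch_trials_per_run
  if (nc == 0) return(trials)
  catch <- data.frame(
    participant = rep(pp$participant, each = nc * cfg$n_runs),
    group = rep(pp$group, each = nc * cfg$n_runs),
    run = rep(rep(seq_len(cfg$n_runs), each = nc), times = nrow(pp)),
    size_deg = max(cfg$sizes),
    contrast = max(cfg$contrasts),
    is_catch = TRUE,
    trial = rep(seq_len(nc), times = cfg$n_runs * nrow(pp)),
    duration_ms = cfg$catch_duration_ms,
    correct = stats::runif(nc * cfg$n_runs * nrow(pp)) <
      rep(acc_pp, each = nc * cfg$n_runs))
  rbind(trials, catch)
}

#' Maximum-likelihood Weibull fit to staircase trials
#'
#' Fits the Weibull psychometric function to trial data by maximum
#' likelihood with guess and lapse rates fixed (0.5 and 0.04), and reads the
#' 80%-correct duration threshold from the fitted curve. A coarse grid
#' search seeds a Nelder-Mead polish in log-parameter space.
#'
#' @param duration_ms,correct Trial durations (ms) and outcomes.
#' @param gamma,lambda Fixed guess and lapse rates.
#' @param polish Refine the grid optimum with [stats::optim()]
#'   (default TRUE).
#' @return An object of class `psychometric_fit`: `alpha`, `beta`,
#'   `threshold80`, `loglik`, `converged`, `n_trials`. Degenerate data (a
#'   single distinct duration, or all-correct / all-incorrect responses)
#'   yield `converged = FALSE` and a missing threshold.
#' @export
fit_weibull <- function(duration_ms, correct, gamma = 0.5, lambda = 0.04,
                        polish = TRUE) {
  stopifnot(length(duration_ms) == length(correct), all(duration_ms > 0))
  correct <- as.logical(correct)
  bad <- length(unique(duration_ms)) < 2 || all(correct) || !any(correct)
  if (bad) {
    return(structure(list(alpha = NA_real_, beta = NA_real_,
                          threshold80 = NA_real_, loglik = NA_real_,
                          converged = FALSE, n_trials = length(correct)),
                     class = "psychometric_fit"))
  }
  nll <- function(par) {
    p <- weibull_p(duration_ms, exp(par[1]), exp(par[2]), gamma, lambda)
    -sum(ifelse(correct, log(p), log(1 - p)))
  }
  # vectorized grid search: binomial log-likelihood over all (alpha, beta)
  # cells from per-duration success counts in two matrix products; the
  # alpha range deliberately extends past the 500 ms exclusion bound so
  # that pathological staircases are flagged by the exclusion rule rather
  # than clamped into the valid range
  ag <- exp(seq(log(2), log(2000), length.out = 97))
  bg <- exp(seq(log(0.5), log(8), length.out = 17))
  grid <- expand.grid(a = ag, b = bg)
  du <- sort(unique(duration_ms))
  k <- vapply(du, function(d) sum(correct[duration_ms == d]), numeric(1))
  n_d <- vapply(du, function(d) sum(duration_ms == d), numeric(1))
  P <- outer(du, seq_len(nrow(grid)), function(d, j)
    weibull_p(d, grid$a[j], grid$b[j], gamma, lambda))
  ll <- crossprod(k, log(P)) + crossprod(n_d - k, log(1 - P))
  best <- grid[which.max(ll), ]
  par <- c(log(best$a), log(best$b))
  val <- -max(ll)
  if (polish) {
    # slope bounded away from degenerate step-function fits
    opt <- stats::optim(par, nll, method = "L-BFGS-B",
                        lower = c(log(1), log(0.25)),
                        upper = c(log(2000), log(16)))
    par <- opt$par
    val <- opt$value
  }
  alpha <- exp(par[1]); beta <- exp(par[2])
  structure(list(alpha = alpha, beta = beta,
                 threshold80 = threshold_from_alpha(alpha, beta, gamma,
                                                    lambda),
                 loglik = -val, converged = TRUE,
                 n_trials = length(correct)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf(paste0("Weibull fit: alpha = %.1f ms, beta = %.2f, ",
                       "80%%-correct threshold = %.1f ms (n = %d)\n"),
                x$alpha, x$beta, x$threshold80, x$n_trials))
  else
    cat(sprintf("Weibull fit: not converged (n = %d, degenerate data)\n",
                x$n_trials))
  invisible(x)
}

#' Fit thresholds for a cohort trial table
#'
#' Fits each individual staircase (participant x condition x run) by
#' maximum likelihood and summarizes each condition as the mean of the
#' per-run fitted 80% thresholds. Unconverged staircases and per-staircase
#' thresholds outside the pre-defined (0, 500\] ms range are dropped before
#' averaging (the range rule operates on individual staircase fits; see
#' [apply_exclusions()] for the participant-level catch-trial rule).
#' Catch trials are not used for fitting.
#'
#' The per-staircase grid search is vectorized across all staircases; set
#' `polish = FALSE` to skip the per-staircase Nelder-Mead refinement when
#' fitting very large simulated cohorts (grid resolution is ~3% in alpha).
#'
#' @param trials Trial table from [simulate_behavior()].
#' @param gamma,lambda Fixed guess and lapse rates.
#' @param polish Refine each staircase fit with [stats::optim()].
#' @return A data frame `participant`, `group`, `size_deg`, `contrast`,
#'   `threshold_ms`, `n_staircases`.
#' @export
fit_thresholds <- function(trials, gamma = 0.5, lambda = 0.04,
                           polish = TRUE) {
  tr <- trials[!trials$is_catch, ]
  key <- interaction(tr$participant, tr$size_deg, tr$contrast, tr$run,
                     drop = TRUE)
  groups <- split(tr, key)
  fits <- lapply(groups, function(g) {
    f <- fit_weibull(g$duration_ms, g$correct, gamma, lambda,
                     polish = polish)
    data.frame(participant = g$participant[1], group = g$group[1],
               size_deg = g$size_deg[1], contrast = g$contrast[1],
               run = g$run[1], threshold_ms = f$threshold80,
               converged = f$converged)
  })
  per_run <- do.call(rbind, fits)
  ok <- per_run$converged & !is.na(per_run$threshold_ms) &
    per_run$threshold_ms > 0 & per_run$threshold_ms <= 500
  n_dropped <- sum(!ok)
  per_run <- per_run[ok, ]
  agg <- stats::aggregate(threshold_ms ~ participant + group + size_deg +
                            contrast, data = per_run, FUN = mean)
  n <- stats::aggregate(cbind(n_staircases = threshold_ms) ~ participant +
                          group + size_deg + contrast, data = per_run,
                        FUN = length)
  out <- merge(agg, n, by = c("participant", "group", "size_deg",
                              "contrast"))
  attr(out, "n_staircases_dropped") <- n_dropped
  out
}

#' Threshold and participant exclusion rules
#'
#' Applies the pre-defined exclusion criteria: fitted thresholds outside
#' (0, 500\] ms are dropped, and participants with below-80% accuracy over
#' their catch trials (40 under the default protocol) are excluded from all
#' analyses. Exactly 80% passes.
#'
#' @param thresholds Per-run or per-condition threshold table with columns
#'   `participant` and `threshold_ms`.
#' @param trials Trial table containing the catch trials (`is_catch`).
#' @return List with `thresholds` (filtered rows for retained participants),
#'   `excluded_participants`, `catch_accuracy` (per participant), and
#'   `n_thresholds_dropped`.
#' @export
apply_exclusions <- function(thresholds, trials) {
  catch <- trials[trials$is_catch, ]
  acc <- tapply(catch$correct, catch$participant, mean)
  excluded <- names(acc)[acc < 0.80]
  ok_thr <- !is.na(thresholds$threshold_ms) &
    thresholds$threshold_ms > 0 & thresholds$threshold_ms <= 500
  kept <- thresholds[ok_thr &
                       !(as.character(thresholds$participant) %in% excluded), ]
  list(thresholds = kept,
       excluded_participants = excluded,
       catch_accuracy = acc,
       n_thresholds_dropped = sum(!ok_thr))
}

#' Size index: log-ratio of medium to big thresholds
#'
#' `size index = log10(threshold_medium) - log10(threshold_big)` at a given
#' contrast, where medium is the 1.7-deg and big the 10-deg condition. More
#' negative indices indicate stronger spatial suppression. The index is
#' invariant to the time unit.
#'
#' @param thresholds A [threshold_surface()] or any data frame with columns
#'   `size_deg`, `contrast` and a threshold column (`threshold` or
#'   `threshold_ms`).
#' @param contrast Contrast level at which to compute the index.
#' @param medium,big Diameters (deg) of the medium and big conditions.
#' @return Scalar size index (NA if either threshold is missing).
#' @export
size_index <- function(thresholds, contrast, medium = 1.7, big = 10) {
  col <- if ("threshold" %in% names(thresholds)) "threshold" else
    "threshold_ms"
  tm <- thresholds[[col]][thresholds$size_deg == medium &
                            thresholds$contrast == contrast]
  tb <- thresholds[[col]][thresholds$size_deg == big &
                            thresholds$contrast == contrast]
  if (length(tm) != 1 || length(tb) != 1 || is.na(tm) || is.na(tb))
    return(NA_real_)
  log10(tm) - log10(tb)
}

#' Per-participant size indices from a threshold table
#'
#' Computes the size index for every participant at each contrast, plus
#' their mean across contrasts.
#'
#' @param thresholds Output of [fit_thresholds()] (or the ground-truth
#'   observer table with a `threshold_ms` column).
#' @return Data frame `participant`, `group`, `contrast`, `size_index`.
#' @export
size_indices <- function(thresholds) {
  keys <- unique(thresholds[, c("participant", "group")])
  contrasts <- sort(unique(thresholds$contrast))
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sub <- thresholds[thresholds$participant == keys$participant[i], ]
    data.frame(participant = keys$participant[i], group = keys$group[i],
               contrast = contrasts,
               size_index = vapply(contrasts, function(cc)
                 size_index(sub, cc), numeric(1)))
  }))
  rownames(out) <- NULL
  out
}
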