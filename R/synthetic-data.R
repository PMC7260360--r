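# Synthetic-cohort generators with known ground truth: model-grounded
# Weibull observers, demographic/clinical tables with a built-in
# suppression-symptom correlation, and block-design BOLD with HRF-convolved
# suppression responses.

#' Cohort specification
#'
#' Describes the synthetic ASD/NT study to generate: group sizes, the model
#' variant each group's observers are built from, between-subject threshold
#' variability, the clinical-score model, the target correlation between
#' sensory symptom scores and the fMRI suppression metric, and the fMRI
#' suppression amplitudes with their between-subject spread.
#'
#' Default group sizes (28 ASD, 35 NT), SRS-2 moments and demographic
#' proportions match the study population this package emulates; the ASD
#' group uses the narrow top-down variant by default. The millisecond calibration
#' `threshold_scale_ms` maps model threshold units to milliseconds so that
#' NT thresholds land in the 50-200 ms range typical of this task.
#'
#' @param n_asd,n_nt Group sizes (>= 2).
#' @param nt_variant,asd_variant Model variants (see [apply_variant()])
#'   generating each group's true thresholds.
#' @param subject_sdlog SD (log scale) of the per-subject lognormal factor
#'   shared across conditions.
#' @param condition_sdlog SD (log scale) of an optional per-condition
#'   lognormal jitter on top of the subject factor. The default of 0 keeps
#'   each group's true size indices identical across subjects (individual
#'   sensitivity varies; the suppression pattern does not).
#' @param threshold_scale_ms Milliseconds per model threshold unit.
#' @param beta Psychometric slope of the synthetic observers.
#' @param catch_accuracy Catch-trial accuracy of the synthetic observers.
#' @param srs2_asd,srs2_nt SRS-2 total score mean and SD per group.
#' @param sensory_rho Target correlation between the sensory
#'   (sensitivity + avoiding) score and the fMRI suppression metric.
#' @param sensory_mean,sensory_sd Moments of the sensory score.
#' @param suppression_mean_asd,suppression_mean_nt True fMRI suppression
#'   amplitudes (% signal change; negative = suppression).
#' @param suppression_sd Between-subject SD of the amplitude.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 28, n_nt = 35,
                        nt_variant = "baseline_nt",
                        asd_variant = "narrow_topdown",
                        subject_sdlog = 0.2, condition_sdlog = 0,
                        threshold_scale_ms = 400,
                        beta = 3, catch_accuracy = 0.97,
                        srs2_asd = c(72.1, 27.0), srs2_nt = c(38.7, 17.8),
                        sensory_rho = 0.34,
                        sensory_mean = 100, sensory_sd = 25,
                        suppression_mean_asd = -0.2,
                        suppression_mean_nt = -0.5,
                        suppression_sd = 0.2) {
  stopifnot(n_asd >= 2, n_nt >= 2, subject_sdlog >= 0,
            condition_sdlog >= 0, threshold_scale_ms > 0,
            sensory_rho > -1, sensory_rho < 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# memoized threshold surfaces: cohort simulation re-evaluates the same
# deterministic model surface many times
.surface_cache <- new.env(parent = emptyenv())
cached_surface <- function(params) {
  key <- paste(unlist(unclass(params)), collapse = "|")
  if (is.null(.surface_cache[[key]]))
    .surface_cache[[key]] <- threshold_surface(params)
  .surface_cache[[key]]
}

#' Model-grounded synthetic observers
#'
#' Builds per-participant, per-condition true 80% thresholds: the model's
#' predicted threshold surface under each group's variant, scaled to
#' milliseconds, multiplied by a per-subject lognormal factor (shared across
#' conditions) and a per-condition lognormal jitter. Groups differ only
#' through their model variant. With both SDs zero, all same-group
#' observers are identical.
#'
#' @param spec A [cohort_spec()].
#' @param params Baseline model parameters ([norm_model_params()]).
#' @param seed Optional integer seed.
#' @return Data frame `participant`, `group`, `size_deg`, `contrast`,
#'   `threshold_ms`, `beta`, `catch_accuracy`.
#' @export
observers_from_model <- function(spec, params = norm_model_params(),
                                 seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  surf <- list(
    asd = cached_surface(apply_variant(params, spec$asd_variant)),
    nt = cached_surface(apply_variant(params, spec$nt_variant)))
  build <- function(group, n) {
    s <- surf[[tolower(group)]]
    subj <- exp(stats::rnorm(n, 0, spec$subject_sdlog))
    do.call(rbind, lapply(seq_len(n), function(i) {
      jit <- exp(stats::rnorm(nrow(s), 0, spec$condition_sdlog))
      data.frame(participant = sprintf("%s%02d", group, i), group = group,
                 size_deg = s$size_deg, contrast = s$contrast,
                 threshold_ms = s$threshold * spec$threshold_scale_ms *
                   subj[i] * jit)
    }))
  }
  out <- rbind(build("ASD", spec$n_asd), build("NT", spec$n_nt))
  out$beta <- spec$beta
  out$catch_accuracy <- spec$catch_accuracy
  rownames(out) <- NULL
  out
}

#' Generate a synthetic cohort table with ground truth
#'
#' Produces the per-participant cohort table: group, sex and handedness
#' (drawn with the emulated sample's demographic proportions), SRS-2
#' scores, a true
#' fMRI suppression amplitude per participant, and a sensory
#' (sensitivity + avoiding) score constructed to correlate with the
#' suppression amplitude at `sensory_rho` across the pooled cohort (weaker,
#' i.e. less negative, suppression pairs with higher sensory scores).
#' Also attaches model-grounded observers ([observers_from_model()]).
#'
#' @param spec A [cohort_spec()].
#' @param params Baseline model parameters.
#' @param seed Optional integer seed; the generator is a pure function of
#'   (spec, params, seed).
#' @return List: `cohort` (one row per participant), `observers`
#'   (per-condition true thresholds) and `truth` (generator inputs).
#' @export
generate_cohort <- function(spec, params = norm_model_params(),
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_asd + spec$n_nt
  group <- c(rep("ASD", spec$n_asd), rep("NT", spec$n_nt))
  id <- c(sprintf("ASD%02d", seq_len(spec$n_asd)),
          sprintf("NT%02d", seq_len(spec$n_nt)))
  # demographic proportions from the study sample
  p_male <- ifelse(group == "ASD", 18 / 28, 21 / 35)
  p_left <- ifelse(group == "ASD", 4 / 28, 2 / 35)
  sex <- ifelse(stats::runif(n) < p_male, "M", "F")
  hand <- ifelse(stats::runif(n) < p_left, "L", "R")
  srs2 <- ifelse(group == "ASD",
                 stats::rnorm(n, spec$srs2_asd[1], spec$srs2_asd[2]),
                 stats::rnorm(n, spec$srs2_nt[1], spec$srs2_nt[2]))
  srs2 <- pmax(srs2, 0)
  supp <- ifelse(group == "ASD", spec$suppression_mean_asd,
                 spec$suppression_mean_nt) +
    stats::rnorm(n, 0, spec$suppression_sd)
  z <- as.vector(scale(supp))
  rho <- spec$sensory_rho
  sens <- spec$sensory_mean + spec$sensory_sd *
    (rho * z + sqrt(1 - rho^2) * stats::rnorm(n))
  observers <- observers_from_model(spec, params)
  list(cohort = data.frame(participant = id, group = group, sex = sex,
                           handedness = hand, srs2 = srs2,
                           sensory_score = sens,
                           suppression_true = supp),
       observers = observers,
       truth = list(spec = spec, params = params, seed = seed))
}

#' BOLD simulation settings
#'
#' Block-design parameters for the synthetic fMRI runs: 25 alternating 10 s
#' blocks (13 smaller, 12 larger) per run at TR = 2 s (125 volumes, 4.2
#' min), an ROI of 40 voxels (both hemispheres pooled), AR(1) Gaussian
#' voxel noise, and the double-gamma haemodynamic response.
#'
#' @param tr Repetition time (s).
#' @param block_s Block duration (s).
#' @param n_blocks Blocks per run (odd count; run starts with a smaller
#'   block).
#' @param n_voxels ROI voxels per run.
#' @param n_runs Runs per contrast condition.
#' @param baseline Raw signal baseline (arbitrary scanner units).
#' @param noise_sd Stationary voxel noise SD, % of baseline.
#' @param ar1 AR(1) coefficient of the voxel noise.
#' @return An object of class `bold_config`.
#' @export
bold_config <- function(tr = 2, block_s = 10, n_blocks = 25, n_voxels = 40,
                        n_runs = 2, baseline = 100, noise_sd = 1,
                        ar1 = 0.4) {
  stopifnot(tr > 0, block_s > 0, n_blocks >= 3, n_voxels >= 1, n_runs >= 1,
            baseline > 0, noise_sd >= 0, ar1 > -1, ar1 < 1)
  structure(as.list(environment()), class = "bold_config")
}

#' Canonical double-gamma haemodynamic response
#'
#' SPM-style double-gamma HRF: a gamma peak at ~5 s minus a 1/6-weighted
#' undershoot gamma peaking at ~15 s.
#'
#' @param t Time (s) since neural onset.
#' @return HRF values (unnormalized).
#' @export
hrf_double_gamma <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# HRF-convolved larger-block regressor, sampled at volume onsets, together
# with its epoch-contrast calibration: the regressor is scaled so that the
# noiseless epoch/PSC pipeline measures exactly `1` for unit amplitude
# (window-minus-baseline contrast of the periodic response = 1).
bold_regressor <- function(cfg) {
  dt <- 0.1
  run_s <- cfg$n_blocks * cfg$block_s
  tt <- seq(0, run_s - dt, by = dt)
  block <- floor(tt / cfg$block_s) + 1
  box <- as.numeric(block %% 2 == 0)      # larger blocks are even-numbered
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tt)] * dt
  vol_times <- (seq_len(run_s / cfg$tr) - 1) * cfg$tr
  reg <- conv[match(round(vol_times / dt), round(tt / dt))]
  reg <- reg / max(abs(reg))
  events <- cfg$block_s * seq(1, cfg$n_blocks - 1, by = 2)
  # noiseless epoch contrast of the unit regressor
  rel <- seq(-4, 10, by = cfg$tr)
  ep <- t(vapply(events, function(ev) {
    vol <- round((ev + rel) / cfg$tr) + 1
    if (any(vol < 1) || any(vol > length(reg))) rep(NA_real_, length(rel))
    else reg[vol]
  }, numeric(length(rel))))
  ep <- ep[stats::complete.cases(ep), , drop = FALSE]
  b0 <- mean(ep[, rel >= -4 & rel < 0])
  w0 <- mean(ep[, rel >= 8 & rel < 12])
  list(reg = reg, events = events, contrast = w0 - b0, base_level = b0)
}

#' Simulate one block-design BOLD run
#'
#' Generates a voxel x time ROI run: the HRF-convolved alternating-block
#' regressor carrying the participant's suppression amplitude, on a flat
#' baseline, plus independent AR(1) Gaussian noise per voxel. The regressor
#' is calibrated in closed form so that the noiseless analysis pipeline
#' (epoching, pooled-baseline percent signal change, 8-12 s window) reads
#' back exactly `amplitude`; amplitudes are therefore in measured-PSC units.
#'
#' @param amplitude True suppression amplitude (% signal change; negative
#'   values suppress the larger-block response below baseline).
#' @param cfg A [bold_config()].
#' @param hemisphere,run Labels stored on the result.
#' @return A [roi_timeseries()] with `event_times` at every
#'   smaller -> larger transition.
#' @export
generate_bold <- function(amplitude, cfg = bold_config(),
                          hemisphere = NA_character_, run = NA_integer_) {
  stopifnot(inherits(cfg, "bold_config"))
  rg <- bold_regressor(cfg)
  # exact calibration including the pooled-baseline division:
  # measured(s) = s * contrast / (1 + s * base_level / 100) = amplitude
  s <- amplitude / (rg$contrast - amplitude * rg$base_level / 100)
  n_vol <- length(rg$reg)
  innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar1^2)
  noise <- vapply(seq_len(cfg$n_voxels), function(v)
    as.numeric(stats::filter(stats::rnorm(n_vol, 0, innov_sd),
                             cfg$ar1, method = "recursive")),
    numeric(n_vol))
  pct <- matrix(s * rg$reg, nrow = cfg$n_voxels, ncol = n_vol,
                byrow = TRUE) + t(noise)
  roi_timeseries(cfg$baseline * (1 + pct / 100), tr = cfg$tr,
                 event_times = rg$events, hemisphere = hemisphere,
                 run = run)
}

#' Simulate and analyze a cohort's fMRI sessions
#'
#' For each participant, simulates `n_runs` BOLD runs at their true
#' suppression amplitude and runs the full analysis pipeline
#' ([analyze_fmri_runs()]) to obtain the measured suppression metric.
#'
#' @param cohort Cohort table from [generate_cohort()] (needs
#'   `participant`, `group`, `suppression_true`).
#' @param cfg A [bold_config()].
#' @param seed Optional integer seed.
#' @return Data frame `participant`, `group`, `suppression_true`,
#'   `suppression_measured`.
#' @export
simulate_fmri_cohort <- function(cohort, cfg = bold_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  meas <- vapply(seq_len(nrow(cohort)), function(i) {
    runs <- lapply(seq_len(cfg$n_runs), function(r)
      generate_bold(cohort$suppression_true[i], cfg, run = r))
    analyze_fmri_runs(runs)
  }, numeric(1))
  data.frame(participant = cohort$participant, group = cohort$group,
             suppression_true = cohort$suppression_true,
             suppression_measured = meas)
}
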