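# End-to-end pipeline: model predictions, synthetic behavior, fMRI metrics
# and the group statistics, written to disk as tidy CSV / JSON with a
# manifest recording the seed and config hash.

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]: the cohort and BOLD
#' specifications, baseline model parameters, the seed, and which stages to
#' run. Can be round-tripped through JSON with [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param cohort A [cohort_spec()].
#' @param params A [norm_model_params()].
#' @param bold A [bold_config()].
#' @param staircase A [staircase_config()].
#' @param seed Integer seed driving every stochastic stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("model", "behavior", "fmri", "stats")`.
#' @param polish_fits Use per-staircase optimizer refinement when fitting
#'   (slower; the grid fit is accurate to ~3%).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            params = norm_model_params(),
                            bold = bold_config(),
                            staircase = staircase_config(),
                            seed = 1,
                            stages = c("model", "behavior", "fmri", "stats"),
                            polish_fits = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(params, "norm_model_params"),
            inherits(bold, "bold_config"),
            inherits(staircase, "staircase_config"),
            is.numeric(seed), length(seed) == 1)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(cohort = cohort, params = params, bold = bold,
                 staircase = staircase, seed = as.integer(seed),
                 stages = stages, polish_fits = polish_fits),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path for the JSON representation.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(cohort = do.call(cohort_spec, v$cohort),
                  params = do.call(norm_model_params, v$params),
                  bold = do.call(bold_config, v$bold),
                  staircase = do.call(staircase_config, v$staircase),
                  seed = v$seed, stages = v$stages,
                  polish_fits = v$polish_fits)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(strip_classes(config), f)
  unname(tools::md5sum(f))
}

write_csv_stamped <- function(df, path, stamp) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", stamp), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic study pipeline
#'
#' Orchestrates the stages end-to-end: model threshold predictions per
#' variant, synthetic-cohort generation, behavioral simulation with
#' staircase fitting / exclusions / size indices, fMRI simulation with the
#' suppression metric, and the group statistics (behavioral size-index
#' test, fMRI suppression test, demographic chi-squares, and the
#' permutation correlation between sensory scores and fMRI suppression).
#' Every output file carries a comment line naming the config hash and
#' seed; outputs are byte-identical across runs with the same config.
#'
#' @param config A [pipeline_config()] or a path to its JSON form.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`model_surfaces`,
#'   `cohort`, `thresholds`, `size_indices`, `fmri`, `stats`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (config$cohort$n_asd < 2 || config$cohort$n_nt < 2)
    stop("configuration error: at least 2 participants per group required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("spatsupp config=%s seed=%d", config_hash(config),
                   config$seed)
  res <- list()
  set.seed(config$seed)

  if ("model" %in% config$stages) {
    variants <- c("baseline_nt", "weaker_normalization", "larger_sf",
                  "narrow_topdown", "extra_narrow_topdown")
    surfaces <- do.call(rbind, lapply(variants, function(v) {
      s <- threshold_surface(apply_variant(config$params, v))
      s$variant <- v
      s
    }))
    res$model_surfaces <- surfaces
    write_csv_stamped(surfaces, file.path(out_dir, "model_thresholds.csv"),
                      stamp)
  }

  gen <- generate_cohort(config$cohort, config$params,
                         seed = config$seed)
  res$cohort <- gen$cohort

  excl <- NULL
  if ("behavior" %in% config$stages) {
    trials <- simulate_behavior(gen$observers, config$staircase)
    fits <- fit_thresholds(trials, polish = config$polish_fits)
    excl <- apply_exclusions(fits, trials)
    si <- size_indices(excl$thresholds)
    res$thresholds <- excl$thresholds
    res$size_indices <- si
    res$exclusions <- excl[c("excluded_participants",
                             "n_thresholds_dropped")]
    write_csv_stamped(excl$thresholds,
                      file.path(out_dir, "thresholds.csv"), stamp)
    write_csv_stamped(si, file.path(out_dir, "size_indices.csv"), stamp)
  }

  if ("fmri" %in% config$stages) {
    keep <- if (is.null(excl)) gen$cohort else
      gen$cohort[!(gen$cohort$participant %in%
                     excl$excluded_participants), ]
    fmri <- simulate_fmri_cohort(keep, config$bold)
    res$fmri <- fmri
    write_csv_stamped(fmri, file.path(out_dir, "fmri_suppression.csv"),
                      stamp)
  }

  if ("stats" %in% config$stages) {
    st <- list(seed = config$seed)
    if (!is.null(res$size_indices)) {
      si_mean <- stats::aggregate(size_index ~ participant + group,
                                  data = res$size_indices, FUN = mean)
      tt <- two_sample_t(si_mean$size_index[si_mean$group == "ASD"],
                         si_mean$size_index[si_mean$group == "NT"])
      st$size_index_group <- unclass(tt)
      st$size_index_means <- tapply(si_mean$size_index, si_mean$group,
                                    mean)
    }
    if (!is.null(res$fmri)) {
      tt <- two_sample_t(
        res$fmri$suppression_measured[res$fmri$group == "ASD"],
        res$fmri$suppression_measured[res$fmri$group == "NT"])
      st$fmri_suppression_group <- unclass(tt)
      pc <- permutation_correlation(
        gen$cohort$sensory_score[match(res$fmri$participant,
                                       gen$cohort$participant)],
        res$fmri$suppression_measured)
      st$sensory_fmri_correlation <- pc
    }
    sex_tab <- table(gen$cohort$group, gen$cohort$sex)
    hand_tab <- table(gen$cohort$group, gen$cohort$handedness)
    if (all(dim(sex_tab) == 2) && all(colSums(sex_tab) > 0))
      st$sex_chisq <- unclass(chi_square_2x2(unclass(sex_tab)))
    if (all(dim(hand_tab) == 2) && all(colSums(hand_tab) > 0))
      st$handedness_chisq <- unclass(chi_square_2x2(unclass(hand_tab),
                                                    yates = TRUE))
    res$stats <- st
    jsonlite::write_json(c(list(config_hash = config_hash(config)), st),
                         file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  summary_lines <- c(
    stamp,
    sprintf("participants: %d ASD, %d NT", config$cohort$n_asd,
            config$cohort$n_nt),
    if (!is.null(res$exclusions))
      sprintf("excluded participants: %d; thresholds dropped: %d",
              length(res$exclusions$excluded_participants),
              res$exclusions$n_thresholds_dropped),
    if (!is.null(res$stats$size_index_means))
      sprintf("mean size index: ASD %.3f, NT %.3f (p = %.3g)",
              res$stats$size_index_means[["ASD"]],
              res$stats$size_index_means[["NT"]],
              res$stats$size_index_group$p),
    if (!is.null(res$stats$fmri_suppression_group))
      sprintf("fMRI suppression group test p = %.3g",
              res$stats$fmri_suppression_group$p))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  res$summary <- summary_lines
  invisible(res)
}
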