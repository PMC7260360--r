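# Block-design fMRI suppression analysis: foveal-ROI voxel selection,
# event-locked epoching, percent-signal-change conversion, the 8-12 s
# suppression magnitude and framewise displacement.

#' ROI BOLD time series
#'
#' Container for a voxel x time BOLD matrix with its repetition time and
#' the times (s) at which the stimulus changed from smaller to larger.
#'
#' @param signal Numeric matrix, voxels in rows, volumes in columns.
#' @param tr Repetition time (s), default 2.
#' @param event_times Size-change (smaller -> larger) onset times (s).
#' @param hemisphere,run Optional labels.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(signal, tr = 2, event_times,
                           hemisphere = NA_character_, run = NA_integer_) {
  stopifnot(is.matrix(signal), tr > 0, all(event_times >= 0))
  dur <- ncol(signal) * tr
  if (any(event_times >= dur))
    stop("event times fall outside the run")
  structure(list(signal = signal, tr = tr, event_times = event_times,
                 hemisphere = hemisphere, run = run),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series: %d voxels x %d volumes (TR %g s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$tr, length(x$event_times)))
  invisible(x)
}

#' Select ROI voxels from a significance map
#'
#' Implements the top-k ROI rule: the `k` most significant voxels passing a
#' Bonferroni-corrected threshold (`alpha / n_voxels`); when fewer than `k`
#' pass, the threshold is relaxed so that exactly `k` voxels (the most
#' significant overall) are returned.
#'
#' @param p_values Per-voxel p values for the selection contrast.
#' @param k Voxels to select per hemisphere (default 20).
#' @param alpha Uncorrected significance level before Bonferroni correction.
#' @return Integer indices of the selected voxels, most significant first.
#' @export
select_voxels <- function(p_values, k = 20, alpha = 0.05) {
  n <- length(p_values)
  if (n < k) stop("fewer voxels than the requested ROI size")
  ord <- order(p_values)
  n_sig <- sum(p_values < alpha / n)
  # top-k among corrected-significant voxels; identical to top-k overall
  # once the threshold is relaxed to yield exactly k
  sel <- ord[seq_len(k)]
  attr(sel, "n_significant") <- n_sig
  attr(sel, "relaxed") <- n_sig < k
  sel
}

#' Epoch a time series around size-change events
#'
#' Averages the signal over the selected voxels, then cuts epochs spanning
#' 4 s before to 12 s after each smaller -> larger transition (8 volumes at
#' TR = 2 s; sample times -4, -2, ..., +10 s label the start of each
#' volume). Events whose window would leave the run are dropped and counted.
#'
#' @param ts A [roi_timeseries()].
#' @param voxels Optional voxel indices (e.g. from [select_voxels()]);
#'   default all voxels.
#' @return An object of class `epoch_set`: matrix `epochs`
#'   (epoch x time-in-epoch), sample `times` (s, relative to the event),
#'   `units` ("raw"), and `n_dropped`.
#' @export
extract_epochs <- function(ts, voxels = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sig <- if (is.null(voxels)) ts$signal else ts$signal[voxels, , drop = FALSE]
  roi_mean <- colMeans(sig)
  tr <- ts$tr
  rel <- seq(-4, 10, by = tr)            # 8 volumes covering -4 .. +12 s
  n_vol <- length(roi_mean)
  rows <- lapply(ts$event_times, function(ev) {
    vol <- round((ev + rel) / tr) + 1
    if (any(vol < 1) || any(vol > n_vol)) return(NULL)
    roi_mean[vol]
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no usable events within the run")
  structure(list(epochs = do.call(rbind, rows[keep]),
                 times = rel, units = "raw",
                 n_dropped = sum(!keep)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("Epoch set: %d epochs x %d samples (%g..%g s), units = %s\n",
              nrow(x$epochs), ncol(x$epochs), min(x$times),
              max(x$times) + 2, x$units))
  if (x$n_dropped > 0)
    cat(sprintf("  %d event(s) dropped at run edges\n", x$n_dropped))
  invisible(x)
}

#' Convert epochs to percent signal change
#'
#' The response baseline is the signal averaged over the 0-4 s window before
#' the size change, pooled across *all* epochs; each sample is then
#' converted to `100 * (x - baseline) / baseline`. By construction the mean
#' of the pre-change window across epochs is exactly 0 after conversion.
#'
#' @param epochs An `epoch_set` in raw units.
#' @return The `epoch_set` in percent-signal-change units, with attribute
#'   `baseline`.
#' @export
percent_signal_change <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$units != "raw")
    stop("epochs already converted")
  base_cols <- epochs$times >= -4 & epochs$times < 0
  b <- mean(epochs$epochs[, base_cols])
  if (b == 0) stop("pooled baseline is zero; cannot convert to % change")
  out <- epochs
  out$epochs <- 100 * (epochs$epochs - b) / b
  out$units <- "percent"
  attr(out, "baseline") <- b
  out
}

#' fMRI suppression magnitude
#'
#' The suppression metric: mean percent signal change over the 8-12 s
#' window after the size increase (the period of maximal suppression),
#' averaged across epochs. Negative values indicate suppression of the
#' response below the pre-change baseline.
#'
#' @param epochs_psc An `epoch_set` in percent-signal-change units.
#' @return Scalar suppression magnitude (% signal change).
#' @export
suppression_magnitude <- function(epochs_psc) {
  stopifnot(inherits(epochs_psc, "epoch_set"))
  if (epochs_psc$units != "percent")
    stop("convert to percent signal change first")
  win <- epochs_psc$times >= 8 & epochs_psc$times < 12
  mean(epochs_psc$epochs[, win])
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Per-volume head-motion summary (Power convention): the sum of absolute
#' frame-to-frame differences of the three translations (mm) plus the three
#' rotations (radians) converted to arc length on a 50 mm sphere. The first
#' volume has FD 0 by definition.
#'
#' @param motion Numeric matrix with one row per volume and 6 columns:
#'   3 translations (mm) then 3 rotations (radians).
#' @param radius_mm Sphere radius for the rotation-to-displacement
#'   conversion (default 50 mm).
#' @return List with per-volume `fd` (mm; first element 0) and `mean_fd`
#'   (mean over the displaced volumes).
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  stopifnot(is.matrix(motion), ncol(motion) == 6, nrow(motion) >= 2)
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
  list(fd = c(0, fd), mean_fd = mean(fd))
}

#' Analyze one participant's fMRI session
#'
#' Full per-participant fMRI pipeline: for each run, epoch the ROI-mean
#' time series around size-change events, convert to percent signal change,
#' and take the 8-12 s suppression magnitude; then average across runs (and
#' hemispheres, if runs carry hemisphere labels).
#'
#' @param runs A list of [roi_timeseries()] objects belonging to one
#'   condition (one contrast level).
#' @param voxels Optional voxel selection applied to each run.
#' @return Scalar suppression magnitude (% signal change).
#' @export
analyze_fmri_runs <- function(runs, voxels = NULL) {
  stopifnot(length(runs) >= 1)
  vals <- vapply(runs, function(ts) {
    ep <- percent_signal_change(extract_epochs(ts, voxels))
    suppression_magnitude(ep)
  }, numeric(1))
  mean(vals)
}
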