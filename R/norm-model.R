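# Divisive normalization model of spatial suppression with top-down gain.
#
# The model predicts motion duration thresholds from the population response
# of a space x orientation neural field:
#
#   R = (E * M) / (S_g * S + sigma),    T = C / R_peak
#
# E is the feed-forward excitatory drive, M a top-down (attentional) gain
# field, S the suppressive drive pooling the modulated excitation over a
# spatially broader region, and R_peak the mean response over a central
# readout window. Larger stimuli engage the broad suppressive pool more
# strongly, lowering R_peak and raising the predicted threshold T -- the
# spatial suppression effect.

erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1

#' Stimulus specification
#'
#' A centred circular drifting grating described by its diameter (degrees of
#' visual angle) and Michelson contrast.
#'
#' @param diameter Stimulus diameter in degrees of visual angle (> 0).
#' @param contrast Michelson contrast as a fraction in \[0, 1\].
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(1.7, 0.98)
#' @export
stimulus_spec <- function(diameter, contrast) {
  stopifnot(is.numeric(diameter), length(diameter) == 1, diameter > 0,
            is.numeric(contrast), length(contrast) == 1,
            contrast >= 0, contrast <= 1)
  structure(list(diameter = diameter, contrast = contrast),
            class = "stimulus_spec")
}

#' Normalization-model parameters
#'
#' Builds (and validates) the full parameter set of the divisive
#' normalization model with top-down gain. The committed defaults produce the
#' canonical spatial-suppression pattern (duration thresholds increasing with
#' stimulus size at both low and high contrast) and are the baseline
#' neurotypical ("NT") parameter set that the model variants perturb; see
#' [apply_variant()].
#'
#' Spatial quantities are in degrees of visual angle except the top-down
#' field width `m_width` and the readout width `readout_width`, which are in
#' model units converted to degrees by `unit_scale` (default 0.1 deg per
#' unit, i.e. one grid step of the default spatial axis).
#'
#' @param grid_extent Half-width of the spatial axis (deg). Must cover the
#'   largest stimulus plus suppressive-pool margin.
#' @param grid_step Spatial sampling step (deg).
#' @param n_orient Number of orientation channels tiling 180 deg.
#' @param x_w_e Gaussian width of the excitatory spatial filter (deg).
#' @param o_w_e Orientation tuning width of the excitatory drive (deg).
#' @param x_w_s Spatial width of the suppressive pool (deg); must exceed
#'   `x_w_e`.
#' @param o_w_s Orientation width of the suppressive pool (deg).
#' @param S_g Suppressive gain (dimensionless).
#' @param sigma Semi-saturation constant (> 0).
#' @param m_width Width of the top-down gain field, in model units.
#' @param m_gain Peak top-down gain (>= 1); `m_gain = 1` disables modulation.
#' @param C Criterion response needed for a perceptual decision (> 0).
#' @param readout_width Width of the spatial readout window, in model units.
#' @param unit_scale Degrees per model unit for `m_width`/`readout_width`.
#' @return An object of class `norm_model_params`.
#' @seealso [apply_variant()], [model_response()], [threshold_surface()]
#' @export
norm_model_params <- function(grid_extent = 15, grid_step = 0.1,
                              n_orient = 9,
                              x_w_e = 0.3, o_w_e = 25,
                              x_w_s = 1.5, o_w_s = 60,
                              S_g = 1, sigma = 0.01,
                              m_width = 14, m_gain = 3,
                              C = 1, readout_width = 6,
                              unit_scale = 0.1) {
  p <- list(grid_extent = grid_extent, grid_step = grid_step,
            n_orient = n_orient, x_w_e = x_w_e, o_w_e = o_w_e,
            x_w_s = x_w_s, o_w_s = o_w_s, S_g = S_g, sigma = sigma,
            m_width = m_width, m_gain = m_gain, C = C,
            readout_width = readout_width, unit_scale = unit_scale)
  validate_norm_model_params(p)
  structure(p, class = "norm_model_params")
}

validate_norm_model_params <- function(p) {
  stopifnot(p$grid_extent > 0, p$grid_step > 0, p$n_orient >= 1,
            p$x_w_e > 0, p$o_w_e > 0, p$o_w_s > 0,
            p$sigma > 0, p$C > 0, p$m_width > 0, p$m_gain >= 1,
            p$readout_width > 0, p$unit_scale > 0, p$S_g >= 0)
  if (p$x_w_s <= p$x_w_e)
    stop("suppressive pool width x_w_s must exceed excitatory width x_w_e")
  invisible(p)
}

#' @export
print.norm_model_params <- function(x, ...) {
  cat("Normalization model parameters\n")
  cat(sprintf("  grid: +/-%g deg, step %g deg, %d orientation channels\n",
              x$grid_extent, x$grid_step, x$n_orient))
  cat(sprintf("  excitation: x_w_e = %g deg, o_w_e = %g deg\n",
              x$x_w_e, x$o_w_e))
  cat(sprintf("  suppression: x_w_s = %g deg, o_w_s = %g deg, S_g = %g, sigma = %g\n",
              x$x_w_s, x$o_w_s, x$S_g, x$sigma))
  cat(sprintf("  top-down: m_width = %g units (%g deg), m_gain = %g\n",
              x$m_width, x$m_width * x$unit_scale, x$m_gain))
  cat(sprintf("  readout: width %g units (%g deg), criterion C = %g\n",
              x$readout_width, x$readout_width * x$unit_scale, x$C))
  invisible(x)
}

# Spatial and orientation axes of the neural field.
field_grid <- function(params) {
  x <- seq(-params$grid_extent, params$grid_extent, by = params$grid_step)
  # channels evenly tile the 180-deg cycle; with an odd count one channel
  # sits exactly at the stimulus orientation (0 deg)
  spacing <- 180 / params$n_orient
  theta <- -90 + spacing / 2 + spacing * (seq_len(params$n_orient) - 1)
  list(x = x, theta = theta)
}

neural_field <- function(values, x, theta) {
  stopifnot(is.matrix(values), nrow(values) == length(x),
            ncol(values) == length(theta), all(is.finite(values)))
  structure(list(values = values, x = x, theta = theta),
            class = "neural_field")
}

#' @export
print.neural_field <- function(x, ...) {
  cat(sprintf("Neural field: %d spatial samples (%g..%g deg) x %d orientation channels\n",
              length(x$x), min(x$x), max(x$x), length(x$theta)))
  cat(sprintf("  range of values: [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

# wrapped orientation difference on a 180-deg cycle
orient_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Feed-forward excitatory drive
#'
#' Computes E, the excitatory drive of the neural field: the stimulus extent
#' (an indicator of width `diameter`) convolved with a spatial Gaussian of
#' width `x_w_e`, scaled linearly by contrast, and tuned in orientation by a
#' Gaussian of width `o_w_e` centred on the stimulus orientation (vertical,
#' 0 deg). The spatial convolution is evaluated analytically (erf form), so
#' E is free of stimulus-edge discretization error.
#'
#' @param stim A [stimulus_spec()].
#' @param params A [norm_model_params()].
#' @return A `neural_field` holding E over space x orientation.
#' @export
stimulus_drive <- function(stim, params) {
  stopifnot(inherits(stim, "stimulus_spec"),
            inherits(params, "norm_model_params"))
  if (stim$diameter / 2 + 3 * params$x_w_s > params$grid_extent)
    stop("stimulus (plus suppressive-pool margin) exceeds the spatial grid; ",
         "increase grid_extent")
  g <- field_grid(params)
  r <- stim$diameter / 2
  sw <- sqrt(2) * params$x_w_e
  ex <- stim$contrast * 0.5 * (erf((g$x + r) / sw) - erf((g$x - r) / sw))
  eo <- exp(-orient_diff(g$theta, 0)^2 / (2 * params$o_w_e^2))
  neural_field(outer(ex, eo), g$x, g$theta)
}

#' Top-down gain field
#'
#' Computes M, the multiplicative top-down gain field: a spatial Gaussian of
#' width `m_width` (model units) centred on the stimulus, riding on a
#' baseline of 1, with peak `m_gain`. M is constant across orientation.
#' Narrower fields concentrate the gain on the stimulus centre, engaging
#' less of the (spatially broad) suppressive pool for large stimuli.
#'
#' @inheritParams stimulus_drive
#' @return A `neural_field` holding M (>= 1 everywhere).
#' @export
topdown_field <- function(params) {
  stopifnot(inherits(params, "norm_model_params"))
  g <- field_grid(params)
  w <- params$m_width * params$unit_scale
  mx <- 1 + (params$m_gain - 1) * exp(-g$x^2 / (2 * w^2))
  neural_field(matrix(mx, nrow = length(g$x), ncol = length(g$theta)),
               g$x, g$theta)
}

# row-normalized Gaussian convolution matrix along a linear axis
gauss_conv_matrix <- function(x, width) {
  k <- outer(x, x, function(a, b) exp(-(a - b)^2 / (2 * width^2)))
  k / rowSums(k)
}

# normalized wrapped-Gaussian convolution matrix over orientation channels
orient_conv_matrix <- function(theta, width) {
  k <- outer(theta, theta, function(a, b)
    exp(-orient_diff(a, b)^2 / (2 * width^2)))
  k / rowSums(k)
}

#' Suppressive drive
#'
#' Computes S by pooling the modulated excitatory drive (E x M) with a
#' separable Gaussian of widths `x_w_s` (space) and `o_w_s` (orientation).
#' The suppressive pool sees the *modulated* drive, so a broader top-down
#' gain field recruits more suppression -- the mechanism by which top-down
#' width controls spatial suppression.
#'
#' @param excitation_modulated A `neural_field` holding E x M.
#' @inheritParams stimulus_drive
#' @return A `neural_field` holding S.
#' @export
suppressive_drive <- function(excitation_modulated, params) {
  stopifnot(inherits(excitation_modulated, "neural_field"),
            inherits(params, "norm_model_params"))
  f <- excitation_modulated
  ks <- gauss_conv_matrix(f$x, params$x_w_s)
  ko <- orient_conv_matrix(f$theta, params$o_w_s)
  neural_field(ks %*% f$values %*% t(ko), f$x, f$theta)
}

#' Predicted model response
#'
#' Evaluates R = (E x M) / (S_g * S + sigma) elementwise over the neural
#' field for a given stimulus. `sigma > 0` guarantees a finite response
#' everywhere, including at zero contrast (where R is identically zero).
#'
#' @inheritParams stimulus_drive
#' @return A `neural_field` holding R, with the component fields E, M and S
#'   attached as attributes `"E"`, `"M"` and `"S"`.
#' @export
model_response <- function(stim, params) {
  E <- stimulus_drive(stim, params)
  M <- topdown_field(params)
  EM <- neural_field(E$values * M$values, E$x, E$theta)
  S <- suppressive_drive(EM, params)
  R <- neural_field(EM$values / (params$S_g * S$values + params$sigma),
                    E$x, E$theta)
  attr(R, "E") <- E
  attr(R, "M") <- M
  attr(R, "S") <- S
  R
}

#' Peak-region readout of the model response
#'
#' Averages the response over a central spatial window of width
#' `readout_width` (model units) at the stimulus orientation channel --
#' the population of neurons assumed to be sampled by the decision stage.
#' The window average uses trapezoidal weights so the readout is stable
#' under grid refinement.
#'
#' @param response A `neural_field` from [model_response()].
#' @inheritParams stimulus_drive
#' @return Scalar R_peak (arbitrary units).
#' @export
readout_peak <- function(response, params) {
  stopifnot(inherits(response, "neural_field"),
            inherits(params, "norm_model_params"))
  hw <- params$readout_width * params$unit_scale / 2
  if (hw > params$grid_extent)
    stop("readout window exceeds the spatial grid")
  win <- which(abs(response$x) <= hw + 1e-9)
  if (length(win) < 2)
    stop("readout window narrower than one grid step; decrease grid_step")
  ochan <- which.min(orient_diff(response$theta, 0))
  w <- rep(1, length(win))
  w[c(1, length(win))] <- 0.5
  sum(response$values[win, ochan] * w) / sum(w)
}

#' Predicted duration threshold
#'
#' Reads out the model's duration-threshold prediction T = C / R_peak for a
#' stimulus: the criterion response divided by the peak-region response.
#' Thresholds are in arbitrary model units; only the pattern across sizes
#' and contrasts is interpreted.
#'
#' @inheritParams stimulus_drive
#' @return Scalar T > 0 (arbitrary units).
#' @export
predict_threshold <- function(stim, params) {
  rp <- readout_peak(model_response(stim, params), params)
  if (rp <= 0)
    stop("peak response is zero (zero-contrast stimulus?); ",
         "threshold is unresolvable")
  params$C / rp
}

#' Threshold surface over sizes and contrasts
#'
#' Evaluates the predicted duration threshold for every combination of
#' stimulus size and contrast. Deterministic given the parameters.
#'
#' @inheritParams stimulus_drive
#' @param sizes Stimulus diameters (deg). Defaults to the three task sizes.
#' @param contrasts Michelson contrasts. Defaults to the low/high task pair.
#' @return A data frame of class `threshold_surface` with columns
#'   `size_deg`, `contrast`, `threshold` and attribute
#'   `provenance = "model-predicted"`.
#' @examples
#' ts <- threshold_surface(norm_model_params())
#' size_index(ts, contrast = 0.98)
#' @export
threshold_surface <- function(params, sizes = c(0.84, 1.7, 10),
                              contrasts = c(0.03, 0.98)) {
  stopifnot(length(sizes) > 0, length(contrasts) > 0)
  grid <- expand.grid(size_deg = sizes, contrast = contrasts,
                      KEEP.OUT.ATTRS = FALSE)
  grid$threshold <- mapply(function(d, c)
    predict_threshold(stimulus_spec(d, c), params),
    grid$size_deg, grid$contrast)
  structure(grid, class = c("threshold_surface", "data.frame"),
            provenance = "model-predicted")
}

#' Model variants
#'
#' Perturbs the baseline (NT) parameter set into one of the candidate
#' accounts of weaker spatial suppression in ASD:
#' \describe{
#'   \item{`baseline_nt`}{unchanged copy.}
#'   \item{`weaker_normalization`}{suppressive gain reduced by 25%
#'     (`S_g` 1 -> 0.75).}
#'   \item{`larger_sf`}{excitatory spatial filter 25% wider
#'     (`x_w_e` x 1.25).}
#'   \item{`narrow_topdown`}{top-down field narrowed to 6 model units
#'     (NT baseline 14).}
#'   \item{`extra_narrow_topdown`}{top-down field narrowed to 1-2 model
#'     units (default 2), the regime compared against a 6-unit NT field.}
#' }
#'
#' @param params Baseline parameters ([norm_model_params()]).
#' @param kind One of the variant names above.
#' @param extra_narrow_width Width used by `extra_narrow_topdown` (1 or 2).
#' @return A new `norm_model_params`; the input is not modified.
#' @export
apply_variant <- function(params, kind = c("baseline_nt",
                                           "weaker_normalization",
                                           "larger_sf",
                                           "narrow_topdown",
                                           "extra_narrow_topdown"),
                          extra_narrow_width = 2) {
  stopifnot(inherits(params, "norm_model_params"))
  kind <- match.arg(kind)
  out <- unclass(params)
  if (kind == "weaker_normalization") {
    out$S_g <- out$S_g * 0.75
  } else if (kind == "larger_sf") {
    out$x_w_e <- out$x_w_e * 1.25
  } else if (kind == "narrow_topdown") {
    out$m_width <- 6
  } else if (kind == "extra_narrow_topdown") {
    stopifnot(extra_narrow_width %in% c(1, 2))
    out$m_width <- extra_narrow_width
  }
  validate_norm_model_params(out)
  structure(out, class = "norm_model_params")
}

#' Read or write model parameters as JSON
#'
#' Flat key-value JSON serialization of a parameter set.
#'
#' @param params A `norm_model_params`.
#' @param path File path.
#' @return `read_model_params` returns a `norm_model_params`.
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "norm_model_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(norm_model_params, vals)
}
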