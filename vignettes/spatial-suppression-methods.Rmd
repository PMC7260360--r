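---
title: "Modelling spatial suppression: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial suppression: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatsupp)
```

## The phenomenon and the model

Spatial suppression is the counter-intuitive finding that *larger* moving
stimuli are *harder* to perceive: the minimum presentation duration needed
to judge the drift direction of a grating grows with its size. The standard
mechanistic account is divisive normalization — a neuron's response is its
feed-forward drive divided by the pooled drive of its neighbours — with the
suppressive pool spatially broader than the excitatory field, so large
stimuli recruit proportionally more suppression.

`spatsupp` implements this model over a one-dimensional spatial axis
(adequate because the stimuli are centred circular gratings) crossed with a
bank of orientation channels:

$$R = \frac{E \times M}{S \cdot S_g + \sigma}, \qquad T = \frac{C}{R_\mathrm{peak}}$$

* **E**, the excitatory drive, is the stimulus extent convolved with a
  spatial Gaussian of width `x_w_e` and an orientation Gaussian of width
  `o_w_e`, scaled linearly by contrast. We evaluate the spatial convolution
  analytically (an erf difference) rather than on the grid: the hard
  stimulus edge otherwise aliases against the sampling step, and the
  analytic form is what makes predictions stable to better than 1% under
  grid refinement.
* **M**, the top-down gain field, is a spatial Gaussian of width `m_width`
  riding on a baseline of 1 with peak `m_gain`. We adopt baseline 1
  (gain-only modulation): far from the attended location processing is
  neither amplified nor abolished.
* **S**, the suppressive drive, pools the *modulated* drive `E × M` with a
  separable Gaussian of widths `x_w_s` (space) and `o_w_s` (orientation).
  Pooling `E × M` rather than raw `E` is a deliberate choice: it is what
  makes a *broader* top-down field recruit *more* suppression for large
  stimuli, the mechanism this model family exists to express, and it
  matches the attention-as-normalization architecture the model descends
  from.
* **R_peak** is the mean response over a central spatial window of width
  `readout_width` at the stimulus orientation — a *population* readout. A
  windowed mean rather than a single-sample maximum matters: when the
  top-down field is narrower than the sampled population, the flanks of the
  window lose gain and the readout falls, which is exactly the regime that
  predicts *elevated* thresholds for very narrow attentional fields. The
  window average uses trapezoidal weights so it converges under grid
  refinement.

Model thresholds `T` are in arbitrary units; the package makes no attempt
to calibrate them to milliseconds at the model level, because only the
pattern across sizes and contrasts is meaningful.

### Units of the top-down field

Top-down widths are specified in model units, converted to degrees by one
scale factor (`unit_scale`, default 0.1 deg per unit — one grid step of the
default ±15 deg axis). The canonical settings are then: broad neurotypical
field 14 units, narrow field 6 units, and the extra-narrow regime 1–2 units
compared against a 6-unit reference, with the readout window fixed at 6
units. This keeps the canonical width ratios intact while pinning them to
an explicit spatial scale.

### Committed default parameters

The free parameters (`x_w_e = 0.3`, `x_w_s = 1.5`, `o_w_e = 25`,
`o_w_s = 60` deg, `S_g = 1`, `sigma = 0.01`, `m_gain = 3`, `C = 1`, grid
±15 deg at 0.1 deg) were fixed once, by a coarse qualitative search for a
regime where the baseline model shows the canonical pattern — thresholds
rising with size at both contrasts, higher thresholds at low contrast, and
`sigma` comparable to the pooled suppressive drive at 3% contrast so the
low-contrast response is sub-saturating. All directional predictions of the
model variants are properties of these committed defaults, not of
per-comparison retuning. The three variants perturb exactly one parameter
each: suppressive gain ×0.75, excitatory width ×1.25, or the top-down
width (14 → 6 → 1–2 units).

## The behavioral simulator

Synthetic observers answer a two-alternative direction judgement through a
Weibull psychometric function with guess rate 0.5 and lapse rate 0.04
(both fixed, also during fitting). The adaptive (Psi) staircase maintains a
posterior over a log-spaced grid of Weibull scale (31 points, 5–500 ms)
and slope (9 points, 0.5–8) and proposes, each trial, the duration among a
log-spaced candidate set (20 points, 6.7–333 ms) minimizing the expected
posterior entropy. The protocol mirrors the task: 30 trials per staircase,
six interleaved staircases (3 sizes × 2 contrasts) per run, four runs, and
10 catch trials per run at 333 ms.

All staircases of a cohort advance together in one vectorized engine
(posteriors as rows of a matrix; the entropy minimization reduces to three
matrix products per trial), which is what makes hundred-cohort recovery
studies affordable in pure R. `psi_staircase()` is simply the batch of size
one, so there is a single code path.

Fitting is maximum likelihood with a vectorized grid search (the grid
extends beyond the 500 ms exclusion bound deliberately, so pathological
staircases are *flagged by the exclusion rule* rather than clamped into the
valid range) followed by an optional bounded quasi-Newton polish. The
80%-correct threshold is read from the fitted curve in closed form.
Per-condition thresholds are the mean of the per-staircase fitted
thresholds, after dropping individual staircase thresholds outside
(0, 500] ms — the range rule is applied at the staircase level, where the
pathologies it targets arise. Participants below 80% catch-trial accuracy
are excluded from every downstream analysis; exactly 80% passes.

Suppression is summarized by the size index,
$\log_{10}(T_{1.7°}) - \log_{10}(T_{10°})$ per contrast; more negative
means stronger suppression. The index is invariant to the time unit and to
any common rescaling of both thresholds.

Simulation-based calibration of the protocol puts the per-staircase
threshold estimate near its information limit (roughly 20% SD for 30
two-alternative trials, or ~10% after averaging four runs), so the
package's recovery figures reflect the protocol, not estimator slack.

## The fMRI stage

Runs are 25 alternating 10 s blocks (13 smaller, 12 larger) at TR = 2 s.
The analysis epochs the ROI-mean signal from 4 s before to 12 s after each
smaller→larger transition, converts to percent signal change against a
single baseline pooled over the 0–4 s pre-change windows of *all* epochs
(we read "across all epochs" as pooled per condition), and takes the mean
PSC over the 8–12 s window as the suppression metric. ROI voxels are the
top 20 per hemisphere passing a Bonferroni-corrected p < 0.05, relaxed to
exactly 20 when fewer pass; on the synthetic voxel grid the relaxation is
top-k, since real-space contiguity has no meaning without anatomy. Head
motion is summarized as framewise displacement in the rigid-body
convention: summed absolute frame-to-frame translations plus rotations
converted to arc length on a 50 mm sphere.

The synthetic BOLD generator convolves the block regressor with a
double-gamma HRF and adds AR(1) Gaussian noise per voxel (stationary SD 1%
of baseline, lag-1 coefficient 0.4, 40 voxels). One calibration choice
deserves emphasis: the regressor is rescaled *in closed form* so that the
noiseless analysis pipeline reads back exactly the nominal amplitude.
Amplitudes are therefore defined in measured-PSC units — the generator's
truth is the analysis pipeline's estimand — which removes HRF-shape bias
from recovery comparisons without any empirical tuning. ROI-mean averaging
precedes PSC conversion; the two orders differ only under
voxel-heterogeneous baselines, which the generator does not produce.

## Statistics

The procedures mirror the analysis plan of the emulated study design: 2×2 chi-square with
optional Yates correction (delegated to `stats::chisq.test`), pooled
two-sample t tests (df = n1 + n2 − 2), paired t tests, Bonferroni
adjustment, and a permutation test for Pearson correlations (10,000
label shuffles without replacement; two-tailed on |r|). The permutation p
is reported as (count + 1)/(n_perm + 1) rather than the literal proportion
so that an empirical p of exactly zero cannot be claimed.

The mixed "group × size" design (participants random, nested in groups;
size continuous) is implemented as a two-stage summary-statistic
procedure: per-participant OLS slope against size, then a between-group
pooled t on the slopes (interaction) and on the per-participant means
(group effect), reported as F = t² with (1, n1 + n2 − 2) df. With two
groups and a single continuous covariate the two-stage procedure is the
classical equivalent of the random-intercept mixed model for this
contrast; since the reference F statistics were computed on participant data that
are not redistributable, its acceptance surface here is *calibration* — holding
the type-I error rate at the nominal level under null simulation — rather
than numeric replication. By default group analyses operate on log10
thresholds, consistent with the logarithmic size index.

## The synthetic cohorts

`cohort_spec()` pins the study conditions: 28 ASD and 35 NT participants;
NT observers built from the baseline model, ASD observers from the
narrow-top-down variant; demographic proportions and SRS-2 moments from
the emulated study population; fMRI suppression amplitudes −0.2% (ASD)
vs −0.5% (NT) with 0.2% between-subject SD; and a sensory
(sensitivity + avoiding) score constructed to correlate at r = 0.34 with
the suppression metric across the pooled cohort.

Choices the sources leave open, fixed once here:

* **Threshold calibration**: one global constant (400 ms per model unit)
  maps model thresholds to milliseconds, placing NT thresholds around
  50–200 ms — typical for this task family and comfortably inside the
  staircase range and the 500 ms exclusion bound.
* **Between-subject variability**: a lognormal subject factor
  (SD 0.2 on the log scale) shared across a subject's conditions —
  individual overall sensitivity varies, while each group's true
  suppression *pattern* (and hence true size index) is common to the
  group and differs only through the model variant. An optional
  per-condition jitter (`condition_sdlog`, default 0) lets users add
  within-subject pattern variability; with it, measured size-index
  spread combines true heterogeneity with measurement noise rather than
  measurement noise alone.
* **Observer slope** β = 3, a typical value for duration psychometrics.
* **Sensory scores** are Gaussian (mean 100, SD 25) around the pooled
  z-scored suppression truth; no additional group mean offset is injected,
  so the built-in group separation in suppression is the only source of
  group difference in the score.

What the generator deliberately does *not* emulate: realistic voxel
geometry and spatial noise correlations, scanner drift (the real pipeline
high-pass filters; the generator has no drift), attention lapses beyond a
fixed lapse rate, session effects, or covariate structure (age, IQ, sex
effects are zero). Passing recovery tests therefore demonstrates that the
*procedures* are correct and adequately powered under the stated
conditions — not that they would behave identically on real data.

## Problem sizes and numerical notes

The committed study sizes keep full-protocol simulation affordable: the
acceptance-level checks use 100 observers for staircase recovery, 50
simulations for fMRI amplitude recovery, 1,000 null replicates for
type-I calibration, and 100 synthetic cohorts (28/35 each, full behavioral
protocol plus two BOLD runs per participant) for end-to-end detection.
Degenerate inputs are handled explicitly: zero-contrast stimuli give a
zero response and an "unresolvable threshold" error rather than an
infinite threshold; staircase data with a single distinct duration or
all-identical outcomes are flagged unconverged; zero-variance t tests
return the p = 1 contract when the means agree and an error otherwise; and
ties in the Psi entropy minimization resolve to the first (shortest)
candidate duration for determinism.
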