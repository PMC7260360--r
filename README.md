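# spatsupp

Spatial suppression — the counter-intuitive fact that *larger* moving
stimuli are *harder* to perceive — is a behavioral signature of suppressive
circuits in visual cortex, and is measurably weaker in autistic adults.
`spatsupp` is an R implementation of the computational and analytical
machinery used to study this effect: a divisive-normalization model with a
top-down (attentional) gain field that predicts motion duration thresholds,
a simulator of the adaptive (Psi) staircase task with Weibull psychometric
fitting, the fMRI percent-signal-change suppression metric for block-design
ROI time series, the accompanying statistics, and synthetic ASD/NT cohort
generators with known ground truth so that every stage can be validated by
recovery testing.

The package is aimed at researchers in visual psychophysics and
computational psychiatry who want to explore candidate mechanisms of
atypical suppression (weaker normalization, larger excitatory filters,
narrower attentional gain) or to power and validate analysis pipelines
against simulated cohorts before touching real data.

## The model

The neural field over space `x` and orientation is

```
R = (E × M) / (S · S_g + σ),        T = C / R_peak
```

where `E` is the feed-forward excitatory drive (stimulus extent convolved
with a Gaussian of width `x_w_e`, linear in contrast), `M` is a top-down
gain field (spatial Gaussian of width `m_width` on a baseline of 1), `S`
pools the modulated drive `E × M` over a spatially broader Gaussian
(`x_w_s > x_w_e`), `S_g` is the suppressive gain, and `σ` the
semi-saturation constant. The predicted duration threshold `T` is the
criterion response `C` over the mean response in a central readout window
(`R_peak`). Because `S` pools more drive for larger stimuli, `R_peak`
falls — and `T` rises — with stimulus size: spatial suppression.

Three single-parameter variants probe candidate group differences:
`weaker_normalization` (`S_g` × 0.75), `larger_sf` (`x_w_e` × 1.25) and
`narrow_topdown` / `extra_narrow_topdown` (`m_width` 14 → 6 → 1–2 units).
Only the narrow top-down field reproduces the observed ASD pattern — lower
thresholds specifically for large stimuli, hence less-negative size
indices (`log10(T_medium) − log10(T_big)`).

## Worked example

```r
library(spatsupp)

params <- norm_model_params()          # committed baseline (NT) parameters
threshold_surface(params)
#>   size_deg contrast threshold
#> 1     0.84     0.03 0.2668353
#> 2     1.70     0.03 0.2936327
#> 3    10.00     0.03 0.4618182
#> 4     0.84     0.98 0.1260890
#> 5     1.70     0.98 0.1838335
#> 6    10.00     0.98 0.3535294
```

Thresholds (arbitrary units) grow with size at both contrasts — the
suppression pattern. Size indices quantify it, and the narrow top-down
variant weakens it:

```r
size_index(threshold_surface(params), contrast = 0.98)
#> [1] -0.284001
size_index(threshold_surface(apply_variant(params, "narrow_topdown")), 0.98)
#> [1] -0.2192944   # less negative: weaker suppression
```

A synthetic cohort run end to end (model-grounded observers, full
staircase protocol, Weibull fits, exclusions, fMRI simulation, group
statistics):

```r
cfg <- pipeline_config(seed = 11)
res <- run_pipeline(cfg, "out")
cat(res$summary, sep = "\n")
#> spatsupp config=3907b2dd44833ff758d379a232f74772 seed=11
#> participants: 28 ASD, 35 NT
#> excluded participants: 0; thresholds dropped: 0
#> mean size index: ASD -0.182, NT -0.239 (p = 0.0002)
#> fMRI suppression group test p = 1.11e-08
```

The ASD group (narrow top-down observers) shows less-negative size indices
and weaker (less negative) fMRI suppression — the built-in group effects,
recovered by the measurement pipeline.

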