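# tsgc — comparing groups of time series with mixed models and ARIMA whitening

`tsgc` answers a question that comes up constantly in plant phenotyping
and other dense longitudinal studies: **when in time do the mean curves of
two groups differ?** The motivating data are chlorophyll-fluorescence
series of de-etiolating seedlings — 3 genotypes × 9 seedlings each,
measured every 2 minutes for 4 hours — but the machinery applies to any
panel of complete, regularly sampled series with group structure.

Simple per-timepoint tests are invalid here because within-subject
measurements are strongly autocorrelated. `tsgc` implements a two-stage
model:

1. **Trend stage** — a linear mixed model fitted by maximum likelihood,

   y_ij = b0 + b1·t + b2·t² + Σ_g b_g·1[group_j = g]
          + u0_j + u1_j·t + u2_j·t² + ε_ij,

   with subject-specific random intercept/slope/curvature (u0, u1, u2)
   under an unstructured 3×3 covariance, and group dummies against a
   reference group.
2. **Whitening stage** — each subject's residual series ε_j gets its own
   nonseasonal ARIMA(p_j, d_j, q_j), chosen by a KPSS-based differencing
   rule (d ≥ 1 by default) and a stepwise AICc search over (p, q). The
   one-step fitted values ε̂_ij join the model's fitted values; the
   innovations r_ij = ε_ij − ε̂_ij are the final, white residuals.
3. **Inference** — at every timepoint, every group pair is compared with a
   two-sample t-test on the combined fitted values, Bonferroni-corrected
   across pairs within the timepoint (0.05/3 = 0.01667 for three groups).
   Maximal runs of consecutive significant timepoints become
   **significance windows**, reported in minutes.

A *naive* mode skips stage 2, demonstrating the false positives/negatives
that unmodeled autocorrelation produces. A synthetic-panel generator with
known ground truth (`sim_config()` / `generate_panel()`) backs
parameter-recovery, type-I and window-recovery studies
(`run_operating_characteristics()`).

## Worked example

Simulate a design-scale panel in which group MUT1 sits 0.15 below the
wild-type curve, with strong AR(1) residual noise (φ = 0.8):

```r
library(tsgc)
cfg <- sim_config(n_timepoints = 61, group_offsets = c(-0.15, 0), seed = 42)
sim <- generate_panel(cfg)
sim$panel
#> Panel: 27 subjects x 61 timepoints (1647 observations)
#> Groups: MUT1, MUT2, WT (reference: WT)
#> Sampling interval: 2 min; scaled: FALSE

fit <- fit_lmm(sim$panel)
whiteness_report(fit)
#> Whiteness report: 27 subjects, 1 pass (threshold 0.1)
#> Mean significant-lag fraction: 0.356
#> Overall: FAIL
```

A third of all residual ACF lags are significant — per-timepoint tests on
this fit would be untrustworthy. Whiten and compare:

```r
arima_fits <- fit_all_residuals(fit, p_max = 2, q_max = 2)
arima_fits
#> Per-subject ARIMA fits (27 subjects)
#> order
#> (0,1,0) (0,1,1) (1,1,1) (2,1,2)
#>       8       2      16       1
#> Whitened-residual whiteness: FAIL (mean significant-lag fraction 0.0247)

report <- pairwise_windows(combine_fits(fit, arima_fits), alpha = 0.05)
report
#> Pairwise comparison report (corrected mode)
#> alpha 0.05, 3 comparisons per timepoint, corrected threshold 0.01667
#> Significance windows:
#>       pair start_index end_index start_minutes end_minutes
#>  MUT1-MUT2           1        61             0         120
#>    MUT1-WT           1        36             0          70
#>    MUT1-WT          39        39            76          76
#>    MUT1-WT          41        41            80          80
```

Whitening drops the mean significant-lag fraction from 0.356 to 0.0247
(the "overall" verdict is all-subjects-pass, a deliberately strict rule —
one subject of 27 still sits above 10%). The injected MUT1 offset is
detected against both other groups; as the quadratic trend grows, a
constant offset of 0.15 fades relative to the between-subject spread, so
the MUT1–WT window closes around 70 min. WT–MUT2 (generated identical)
shows no windows.

The same analysis runs end-to-end from a config file via
`run_pipeline()`, or from a shell through the thin CLI at
`inst/scripts/tsgc.R` (`run`, `simulate`, `diagnose` subcommands), which
writes fit summaries, per-subject model lists, ACF grids, window plots
and a JSON manifest.

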