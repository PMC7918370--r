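---
title: "Comparing groups of time series: the two-stage mixed-model + ARIMA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing groups of time series: the two-stage mixed-model + ARIMA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Dense longitudinal phenotyping — the motivating case is chlorophyll
fluorescence of de-etiolating *Arabidopsis* seedlings, measured every 2
minutes for 4 hours (121 timepoints) on 27 seedlings from 3 genotypes —
produces panels of time series in which consecutive measurements on the
same subject are strongly autocorrelated. The scientific question is *when
in time* two groups' mean curves differ. Naive per-timepoint tests ignore
the serial dependence left in model residuals and can report spurious
significance windows or miss real ones.

`tsgc` implements a two-stage remedy followed by per-timepoint inference:

1. **Trend stage.** A Gaussian linear mixed model with a quadratic time
   trend, group dummy offsets against a reference group, and
   subject-specific random intercept, slope and curvature under an
   unstructured 3×3 covariance:

   $$y_{ij} = b_0 + b_1 t_i + b_2 t_i^2 + \textstyle\sum_g b_g\,
   \mathbf{1}[\mathrm{group}_j = g] + u_{0j} + u_{1j} t_i + u_{2j} t_i^2
   + \varepsilon_{ij}.$$

2. **Whitening stage.** Each subject's residual series
   $\varepsilon_j$ is modeled by its own nonseasonal
   ARIMA$(p_j, d_j, q_j)$, selected automatically. The ARIMA one-step
   fitted values $\hat\varepsilon_{ij}$ join the model's fitted values and
   the innovations $r_{ij} = \varepsilon_{ij} - \hat\varepsilon_{ij}$
   become the final residuals, which should be white.

3. **Inference.** At every time index, each unordered group pair is
   compared by a two-sample t-test on the *combined fitted values*
   (trend + ARIMA part) of the subjects in the two groups. Within a
   timepoint, the family of pair comparisons is Bonferroni-corrected:
   with 3 groups the working threshold is $0.05/3 = 0.01667$. Maximal
   runs of consecutive significant indices are reported as significance
   windows in minutes (index 1 is 0 min, index 2 one sampling interval,
   and so on).

A *naive* mode skips stage 2 and tests the smooth trend-stage fitted
values directly; contrasting the two modes demonstrates what unmodeled
residual autocorrelation does to the inference.

## Conventions and assumptions

* **Time scale.** Models use the integer time index $1..T$; minutes are a
  reporting convention (`minutes_of()`), with index 1 at 0 minutes.
  Coefficients are therefore on the index scale.
* **Complete grids.** Every subject must be observed at every index;
  panels with gaps are rejected rather than imputed, because the ARIMA
  stage needs contiguous series.
* **Baseline scaling.** Raw series are divided by their own first value
  (`scale_to_baseline()`), so every series starts at exactly 1 and series
  of different raw magnitude become comparable. Scaling is idempotent and
  requires a positive baseline. A natural-log transform is available
  behind a flag (`read_panel(log_transform = TRUE)`) and off by default.
* **Estimation.** The trend model is fitted by maximum likelihood
  (through `lme4`) so that fixed-structure variants — e.g. adding a cubic
  term — are comparable by AIC; `compare_by_aic()` refuses REML fits,
  whose likelihoods are not comparable across fixed structures. REML is
  available for final variance reporting. The AIC parameter count is the
  number of fixed effects + the 6 free covariance elements + the residual
  variance. Fixed-effect p-values use the normal (z) reference. Group
  enters the fixed part only: with genotype also in the random part the
  model is over-parameterized for designs of this size and does not
  converge reliably. Optimizer settings are `lme4` defaults; a boundary
  (singular) covariance estimate is recorded on the fit object rather
  than perturbed.

## Diagnostics

The sample ACF uses the standard biased estimator (lag-0 value exactly 1)
with the white-noise band $\pm 1.96/\sqrt{n}$; the default maximum lag is
$\min(10\log_{10} n,\, n-1)$, a common plotting convention. A subject's
residual series counts as white when at most 10% of tested lags fall
outside the band — under true whiteness about 5% do by chance, so the 10%
default leaves headroom while still failing any real AR structure
decisively. Note that with ~20 tested lags a truly white subject still
fails this per-subject rule with probability ≈ 0.1, so for many-subject
panels the *mean* significant-lag fraction is the robust summary; the
per-subject table is retained for plotting and inspection.

Trend screening and differencing-order selection use a KPSS test of level
stationarity (Bartlett-kernel long-run variance, truncation
$\lfloor 3\sqrt{n}/13 \rfloor$, p-values interpolated from the standard
critical-value table and clamped to $[0.01, 0.10]$). KPSS is the natural
choice here because the automated order-selection family this stage
follows chooses $d$ by unit-root/stationarity testing.

## The ARIMA stage

* **Differencing floor.** `min_d = 1` by default: empirically, trends
  survive the quadratic trend stage in this kind of data, and first
  differencing is the standard cure. `choose_d()` starts at the floor and
  keeps differencing (up to 2) while KPSS rejects stationarity at 5%.
* **Order search.** `stepwise_select()` is a Hyndman–Khandakar-style
  neighborhood search minimizing AICc (AIC/BIC selectable): anchors
  $(0,d,0), (1,d,0), (0,d,1), (2,d,2)$, moves of ±1 on $p$ or $q$ within
  bounds (default 5), and toggling of the constant term, which is a mean
  for $d=0$, a linear drift regressor for $d=1$, and absent for $d=2$.
  Exact ties prefer smaller $p+q$, then smaller $p$. On bounded grids the
  search lands within 2 AICc units of exhaustive enumeration (tested).
* **Fitting.** Exact Gaussian likelihood via `stats::arima`
  (CSS-initialized, with a plain-ML fallback), stationarity enforced by
  the optimizer's parameter transform. Fitted values are in-sample
  one-step predictions, so `fitted + residuals` reconstructs the input
  exactly — the additive decomposition the combined model relies on.
  Seasonal slots (P, D, Q, S) exist on the order container for interface
  completeness, but the pipeline fits nonseasonal models only.

## Inference details

The tested samples at a timepoint are the per-subject combined fitted
values, not raw observations. The default test is pooled-variance
(Welch behind `var_equal = FALSE`); degenerate cases follow explicit
conventions (both groups constant and equal → p = 1; constant and unequal
→ p = 0, flagged). Multiplicity is corrected per timepoint across pairs
(0.05/3 for three groups); an optional family across pairs × timepoints
is available but off by default, mirroring standard practice for this
design. Width-one windows are reported as such.

One caveat is inherited from the operational definition: fitted values
are model outputs, not independent raw draws, so the t reference
distribution is approximate. The simulations below show the corrected
pipeline's per-timepoint level is close to nominal under the generator's
assumptions.

## The synthetic generator

`sim_config()`/`generate_panel()` produce panels with exactly the
structure the method assumes, plus ground truth. Defaults encode the
motivating study design and the scale of a fitted chlorophyll
de-etiolation dataset:

| parameter | default | meaning |
|---|---|---|
| design | 3 groups × 3 experiments × 3 replicas | 27 subjects, 9 per group |
| `n_timepoints` | 121 | 2-min sampling over 4 h |
| `fixed_effects` | (0.09175, 0.04297, −1.961e-4) | quadratic trend on the index scale |
| `group_offsets` | (−0.1914, 0.01083) | non-reference group shifts |
| `random_sd` | (0.0625, 4.385e-3, 2.937e-5) | subject intercept/slope/curvature SDs |
| `random_cor` | (−0.65, 0.58, −0.97) | unstructured covariance correlations |
| `noise` | AR(1), φ = 0.8, innovation SD 0.0363 | strong within-subject autocorrelation |

φ = 0.8 makes the trend-stage residuals fail whiteness in essentially
every subject, the situation the whitening stage exists for. A
`localized_effect` adds a group offset over a minute window only, giving
a bounded true difference window for recovery studies;
`true_difference_set()` derives each pair's truly-different indices from
the mean curves. Baseline scaling, when enabled, is applied after noise
injection — as it would be on measured data — so the post-scaling mean
curves (also stored in the ground truth) differ slightly from the
generative coefficients. Subjects are generated independently; the
generator does not emulate measurement dropouts, non-quadratic (e.g.
sigmoidal) growth, heteroscedastic instrument noise, or outliers, so
passing simulation studies speak to the method's statistical behavior
under its own assumptions, not to robustness against those features.

## Study sizes used by the test suite

Simulation-backed checks run at sizes chosen to finish in minutes on one
core while keeping Monte-Carlo error small relative to the tolerances
asserted: whiteness restoration at the full design scale (27 × 121);
fixed-effect/BLUP recovery at full scale over 200 replicates with IID
noise (the generative assumption of the trend stage); type-I studies on
null panels at 27 × 61 over 200 replicates; window recovery (effect of
5.1× the marginal noise SD on minutes 20–60) at 27 × 61 over 100
replicates. The ARIMA search bound is `p_max = q_max = 2` in these
studies — after forced differencing of AR(1)-contaminated residuals the
selected orders never exceed 2 in practice.

## Known limitations

* Under a *pure null* with valid marginal tests, the naive mode's excess
  false positives arrive as rare, long spurious runs (its smooth fitted
  curves make the whole grid behave like one test), while the corrected
  mode scatters small counts across the grid. Mean rejection rates order
  as expected (naive > corrected), but in any single null replicate the
  naive analysis often flags nothing at all; the naive mode's distortion
  is most visible at window edges when real effects exist, and in the
  occasional replicate with a long spurious window.
* No FDR or permutation-based multiplicity control; no correction across
  timepoints by default.
* Seasonal ARIMA terms are interface-only; series with genuine
  periodicity need a different residual model.
* The quadratic trend suits growth that is smooth and roughly
  exponential-saturating over the observation window; groups with
  qualitatively different growth shapes need a richer fixed part
  (`include_cubic` is a first step, selectable by AIC).
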