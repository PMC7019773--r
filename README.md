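# cima — Computer-based Infant Movement Assessment

`cima` is an R package for screening infant spontaneous movements for early
cerebral palsy (CP) risk from tracked 2-D body-part trajectories. Around
9–15 weeks corrected age, infants who later develop CP tend to show
spontaneous movements with reduced complexity: less covariation between body
parts and less modulation of movement frequencies and amplitudes. The
package quantifies this by decomposing the 12 trajectory channels (head,
trunk, both arms, both legs; horizontal and vertical pixel coordinates) into
adaptive time–frequency modes and classifying every 5-second period of the
recording, yielding a per-video **proportion of periods with CP risk-related
movements**. It is aimed at researchers in infant motor assessment who have
trajectory data (from optical-flow tracking, pose estimation, or a
simulator) and want a reproducible, leakage-safe risk model with full
diagnostic statistics.

## The model

For a recording \(x(t) \in \mathbb{R}^{12}\) sampled at `fps` frames/s:

1. **MEMD**: multivariate empirical mode decomposition via directional
   envelope averaging on the unit 11-sphere produces scale-aligned intrinsic
   mode functions \(c_k(t)\), \(k = 1..11\) (zero-padded/truncated to a fixed
   depth), with \(\sum_k c_k + r = x - \bar x\) to machine precision.
2. **Hilbert–Huang spectra**: per mode and channel, instantaneous amplitude
   \(a(t) = |c(t) + i\,\mathcal{H}c(t)|\) and frequency
   \(f(t) = \frac{1}{2\pi}\frac{d\varphi}{dt}\) (smoothed, clipped to
   \([0, \mathrm{fps}/2]\)).
3. **990 features per 5-s window**: per scale, the amplitude-weighted mean
   frequency and mean amplitude of each of the 12 channels plus the Pearson
   correlation of all 66 channel pairs' IMFs — \((12+12+66)\times 11 = 990\).
4. **Window classifier**: standardization → 5-component PLS1 regression with
   VIP-ranked backward feature elimination (set size chosen by honest inner
   cross-validation) → 5 composite scores → linear discriminant with equal
   priors. Window labels are averaged per video; videos with a proportion
   \(\geq 50\%\) are called positive.

Performance is estimated by subject-grouped, outcome-stratified **double
cross-validation** (selection inside each outer-training set, one
out-of-fold prediction per video) with sensitivity/specificity/PPV/NPV
(Clopper–Pearson 95% CIs), ROC/AUC (bootstrap CI), Kruskal–Wallis and
Wilcoxon rank-sum group comparisons with Bonferroni correction, and a
center-of-motion variability baseline (`csd_baseline`) for comparison.

## Worked example

Simulate a labeled cohort, extract windowed features, and cross-validate:

```r
library(cima)

coh   <- simulate_cohort(40, cp_fraction = 0.25, seed = 7, duration_s = 60)
feats <- lapply(coh$trajectories, extract_features, n_dirs = 24)
feats <- list(features = do.call(rbind, lapply(feats, `[[`, "features")),
              meta     = do.call(rbind, lapply(feats, `[[`, "meta")))

cv <- run_double_cv(feats, coh$labels,
                    cv_config(outer_folds = 5, inner_folds = 3, seed = 1,
                              refit_final = FALSE),
                    cima_cfg(drop_frac = 0.5, min_features = 20,
                             inner_folds = 3, seed = 1),
                    n_boot = 500)
print(cv)
#> <cv_report> 40 videos, 5 outer folds
#> confusion: tp=10 fp=0 tn=28 fn=2
#>   sensitivity  83.3% [51.6, 97.9]
#>   specificity 100.0% [87.7, 100.0]
#>   ppv         100.0% [69.2, 100.0]
#>   npv          93.3% [77.9, 99.2]
#>   fnr          16.7% [2.1, 48.4]
#>   fpr           0.0% [0.0, 12.3]
#>   accuracy     95.0% [83.1, 99.4]
#>   prevalence   30.0% [16.6, 46.5]
#> pooled AUC 1.000
```

Here 12 of 40 synthetic videos carry the CP-risk phenotype; out of fold, 10
are flagged (proportion of risk windows ≥ 50%) and the two misses are
low-severity videos whose recordings spend most of their time in typical
dynamics — the same mechanism by which mild, ambulatory CP shows lower risk
proportions than severe, non-ambulatory CP. `cv$videos` holds each video's
out-of-fold proportion for plotting; `train_cima()` /
`classify_windows()` / `write_model()` train, apply and persist a deployable
model, and `group_tests()` compares proportions across clinical groupings.

A command-line front end over the same functions is installed at
`inst/cli/cima` (subcommands `simulate`, `extract`, `train`, `predict`,
`evaluate`, `crossval`).

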