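---
title: "Methods: windowed time-frequency assessment of infant movement trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed time-frequency assessment of infant movement trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Infants at high risk of cerebral palsy (CP) show characteristic changes in
their spontaneous movements months before a clinical diagnosis is possible:
reduced complexity and variability, reduced covariation between body parts,
and reduced modulation of movement frequencies and amplitudes. `cima`
implements a computer-based movement assessment that turns 2-D pixel
trajectories of six body parts (head, trunk, both arms, both legs; x and y
per part, 12 channels in total) into a single interpretable risk statistic:
the **proportion of 5-second periods containing CP risk-related movements**.
A video whose proportion reaches 50% is called positive.

The pipeline has four stages:

1. **Multivariate empirical mode decomposition (MEMD).** The 12 channels are
   decomposed jointly into intrinsic mode functions (IMFs), scale-aligned
   across channels: the signal is projected onto a fixed low-discrepancy set
   of unit directions; for each projection the upper/lower extrema envelopes
   are interpolated with natural cubic splines; the envelope midlines are
   averaged over directions and subtracted (sifting) until the remainder is
   an IMF. Unlike Fourier or wavelet bases, the modes adapt to the recording
   itself.
2. **Hilbert spectral analysis.** Each IMF yields an instantaneous amplitude
   (modulus of the analytic signal, pixels) and an instantaneous frequency
   (smoothed derivative of the unwrapped phase, Hz, clipped to `[0, fps/2]`).
3. **Windowed features.** In non-overlapping 5-s windows, per scale:
   amplitude-weighted mean frequency and mean amplitude of each channel, and
   the within-window Pearson correlation of every unordered channel pair's
   IMFs. With 11 scales this gives (12 + 12 + 66) x 11 = **990 features per
   window**.
4. **Window classifier.** Features are standardized; a 5-component PLS1
   regression of the window class (inherited from the video's CP outcome)
   drives a backward feature elimination ranked by VIP scores; the selected
   features are reduced to the 5 PLS latent-variable **composite scores**;
   a linear discriminant (class means, pooled covariance, equal priors)
   labels each window. Window labels are averaged per video into the
   proportion statistic.

Model selection and performance estimation use **double (nested)
cross-validation** with strict subject grouping: the feature set is chosen by
inner cross-validation inside each outer training set, and every video
receives exactly one out-of-fold prediction.

## Feature layout

The 990-column layout is fixed by arithmetic: 12 per-channel mean
frequencies + 12 mean amplitudes + C(12,2) = 66 pairwise covariations, per
scale, at 11 scales. The stack is zero-padded or surplus modes are folded
into the residue so every recording yields exactly 11 scales, because the
natural decomposition depth varies with recording length while the
downstream regression needs a fixed-length vector. `feature_manifest()`
publishes the mapping from column names `f0001..f0990` to kind, scale and
channel(s); the manifest is part of the model-file contract, and a frozen
model refuses feature tables whose manifest differs. Covariation is defined
on same-scale IMF pairs (not on instantaneous amplitudes and not on raw
coordinates), which measures scale-specific coupling of body parts directly;
the manifest isolates this choice so an alternative definition would be a
drop-in change.

## Backward elimination without self-selection bias

A naive elimination loop that ranks features on the full training set and
then scores the surviving set by cross-validation overestimates the
validation AUC, because the validation windows helped choose the set. `cima`
therefore replays the whole elimination path **inside each inner-training
fold**: per fold, the PLS fit, its VIP ranking, and the next (20% smaller)
feature set are computed from the inner-training windows only, and
out-of-fold predictions are recorded at every set size. Pooled predictions
give an honest AUC-versus-size curve; the winning size (ties go to the
smaller set) is then re-materialized by a deterministic VIP elimination on
the full training data. Under pure-noise features this construction yields
chance-level inner AUC, which the test suite asserts.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_s` | 5 s | feature window; also the unit of the proportion statistic |
| `n_dirs` | 64 | projection directions on the 11-sphere (>= 2 x channels) |
| `max_sift` | 10 | sifting iterations per IMF, with a Cauchy stoppage ratio of 0.2 |
| `max_imfs` | 11 | fixed scale count (see feature layout) |
| `ncomp` | 5 | PLS components = composite scores |
| `drop_frac` | 0.2 | fraction of remaining features dropped per elimination step |
| `priors` | equal | LDA class priors; equal priors counter the roughly 10:1 window imbalance between non-CP and CP windows |
| `window_threshold` | 0.5 | posterior threshold for labelling a window |
| `video_threshold` | 0.5 | proportion threshold for the video decision; a proportion exactly at the threshold classifies positive (the tie is not defined by the decision rule's verbal description, so the >= convention is documented and configurable) |
| `outer_folds` / `inner_folds` | 10 / 5 | double-CV structure, stratified by CP status and grouped by subject |

All frequency features are computed in Hz, so results are robust to the
frame rate (checked at 25 vs 30 fps). Feature standardization absorbs pixel
scale, so camera zoom and body size do not affect the classifier; the
center-of-motion baseline optionally normalizes by head-trunk distance for
the same reason.

## The synthetic cohort generator

No public dataset of tracked infant body-part trajectories exists, so the
package ships a generator that emulates the statistical structure the
pipeline assumes, making every stage testable end to end:

* **Typical (fidgety-like) movements**: every frequency band (defaults
  0.1-0.5, 0.5-1.5, 1.5-3, 3-6 Hz) is active; each band-limited oscillator
  has Ornstein-Uhlenbeck-driven frequency and amplitude modulation
  (`mod_depth` 0.6); channels share a band-wise common component giving
  moderate, slowly drifting inter-channel correlation (`cross_corr` 0.3).
  The oscillator construction was chosen precisely because MEMD demonstrably
  separates its scales.
* **Risk (reduced-variability) movements**: only the two slowest bands are
  active, modulation depth shrinks by `(1 - 0.8 severity)`, and the
  cross-channel synchrony is static and strong (`0.6 + 0.35 severity`).
* **Severity** in `[0, 1]` is the fraction of 5-s blocks (window-aligned,
  half-second crossfades) generated from risk dynamics, so a video's
  expected risk proportion tracks its severity — mirroring the observed
  continuum in which children with non-ambulatory CP show higher risk
  proportions than ambulatory ones.
* **Cohorts**: one video per subject; CP status Bernoulli at 11% prevalence;
  durations 60-300 s with mode and median 300 s; GMFCS levels derived from
  severity quintiles (I-III flagged ambulatory); fidgety-movement classes
  attached as plausible categorical metadata. The default severity
  distribution `rbeta(4, 1.5)` is right-skewed so that only a small minority
  of CP videos fall below the 50% threshold, as in the cohort the generator
  emulates.

What the generator does **not** model: biomechanics (limb lengths, joint
constraints), sleep/cry state changes, tracking dropouts and camera motion,
and any overlap between the phenotypes' feature distributions beyond the
shared typical-dynamics blocks. Synthetic separations are therefore cleaner
than clinical reality; passing tests demonstrate that the pipeline recovers
structure it is designed for, not that it would reach the same accuracy on
real videos.

## Numerical choices

* Channels are mean-centered before decomposition; the trend stays in the
  residue and never enters features. The IMF stack reconstructs the centered
  input to ~1e-14 relative error by construction, asserted at 1e-8.
* Envelope splines are natural cubic with up to two extrema mirrored about
  each boundary; a direction contributes only if its projection has at least
  two maxima and two minima, and decomposition stops when fewer than half
  the directions remain usable. A constant recording returns zero modes and
  a warning.
* Instantaneous frequency uses a centered phase-difference smoothed by a
  0.5-s moving average; samples with amplitude below 1e-12 of the scale's
  peak get frequency 0. Window correlations are 0 when either segment has
  zero variance (this also zeroes all features of padded scales).
* A singular pooled LDA covariance is ridge-regularized with
  `1e-6 x trace/5` and a warning; if all features are constant the model
  degenerates to an explicit majority-class classifier rather than failing.
* Confidence intervals: exact binomial (Clopper-Pearson via beta quantiles)
  for proportions — this reproduces the published sensitivity bracket for
  38/41 exactly — and a stratified percentile bootstrap (2000 replicates)
  for AUC. ROC areas are computed by the trapezoidal rule, which with the
  threshold-sweep construction equals the rank (Mann-Whitney) formulation
  under ties; the equality is asserted at 1e-12.
* Pairwise rank-sum tests use exact enumeration when both groups have at
  most 20 untied observations and the normal approximation with tie
  correction otherwise, with Bonferroni correction across pairs.

## Design decisions on open points

* "Composite scores" are implemented as the 5 PLS latent-variable scores:
  standard PLS-DA practice, consistent with using PLS for selection, and it
  yields exactly five scores. The alternative (clustering selected features
  into five groups and averaging) is isolated behind `composite_scores()`.
* The inner model-selection split is an inner cross-validation (not a fixed
  held-out set); out-of-fold predictions are always what the evaluation
  reports.
* The deployable model is refit on all data with the elimination targeting
  the modal outer-fold feature count (`refit_final`), the standard
  double-CV deployment convention.
* The permutation-null check of the CV harness averages the pooled AUC over
  three independent subject-level label permutations: a single permutation's
  AUC has a standard error of about 0.06 at 200 videos with 15% prevalence,
  so averaging keeps the check powered against leakage rather than against
  permutation luck.
* Readers optionally interpolate missing-value runs of at most 0.5 s
  (`interpolate_gaps`), off by default; anything longer is an error, as is
  any recording shorter than one full window.

## Problem sizes used by the test suite and acceptance script

Simulation-backed checks run on 60-s videos at 30 fps with 24 projection
directions and a 0.5 elimination drop fraction (3 inner folds), which keeps
the full suite under five minutes while exercising every code path at
production shapes (12 channels, 990 features, 11 scales). The evaluation
cohort is 200 videos (15% CP, severity 0.9) for the cross-validation checks
and 150 videos at 11% prevalence in the acceptance script; the pure-tone and
five-minute extraction checks use full defaults (300 s, 64 directions).
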