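---
title: "Methods: synthetic polysomnography, feature-based sleep staging, and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic polysomnography, feature-based sleep staging, and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`somnostage` implements a complete EEG sleep-staging and sleep-architecture
comparison pipeline: 30-s-epoch feature extraction (20 features),
decision-tree feature selection, one-vs-rest SVM staging, hypnogram summary
metrics, and two-group statistics — together with a synthetic
polysomnography generator that provides ground-truth-labelled input for
every stage of the pipeline. This vignette describes the models, the
parameter choices, and their limitations.

## The synthetic polysomnography generator

### Stage dynamics

Hypnograms are generated by a **semi-Markov bout model** over the five AASM
stages (wake `N0`, `N1`–`N3`, `REM`, scored in 30-s epochs). A stage dwells
for `1 + Poisson(d - 1)` epochs (mean `d`, per-stage) and then jumps
according to an embedded transition matrix with zero diagonal. A per-epoch
Markov chain was rejected because geometric single-epoch sojourns produce
unrealistically fragmented hypnograms; the bout model lets NREM–REM cycles
emerge with realistic bout lengths.

The night starts with a wake run realizing the sampled sleep-onset latency
(truncated normal, default mean 26 min, SD 6 min), whose final ~30% is
drowsy `N1`; the first post-latency epoch is `N2`, matching the convention
that sleep onset is the first N2 epoch. Default mean bouts are `N0` 2,
`N1` 4, `N2` 20, `N3` 16, `REM` 14 epochs, and the default transition
matrix routes N1→N2→{N3, REM} with N3→N2→REM returns, so complete
N1→N2→N3→REM cycles occur in any recording of a few hours. The default
collection time is 9 h (1080 epochs), the experiment's lights-off to
lights-on window. `n_cycles` is retained as a descriptive, validated field
(approximate expected cycle count implied by the dwell means); it does not
parameterize the simulation directly.

Because the stationary distribution π of the embedded chain is available in
closed form, expected stage composition is analytic: the long-run fraction
of epochs in stage *s* is π_s d_s / Σ π_u d_u. `calibrate_n3_dwell()`
inverts this for the N3 bout length, with a finite-night correction for the
pre-onset N1 run and the post-onset wake fraction; across 200 simulated
nights the realized mean N3% lands within a few tenths of a point of the
target. At the default parameters the generator produces nights with
roughly 24% N3, 54% N2, SOL ≈ 26 min, and a night-to-night N3% SD of about
4.1 points (estimated once from 200 nights); that SD is the unit used to
inject standardized group effects below.

### EEG synthesis

Each EEG channel is a sum of six band-limited noise tracks (sub-δ 0–1.5,
δ 1.5–4, θ 4–8, α 8–13, β 13–25, γ 25–40 Hz; 4th-order Butterworth-filtered
white noise, unit SD), weighted per epoch by the stage's spectral template
and scaled to a per-stage RMS amplitude (wake 40 µV α-dominant, N1 30 µV
θ, N2 45 µV θ with 13-Hz spindle bursts and biphasic K-complexes, N3 75 µV
δ-dominant, REM 25 µV mixed θ/β). Weights crossfade over 1 s at epoch
boundaries, so there are no amplitude discontinuities beyond the noise
scale. Two EOG channels carry low-frequency noise plus slow-eye-movement
bursts in wake/N1/REM. Every stage has a unique dominant band by
construction, which is what makes staging learnable from spectral features.

**What this emulates and what it does not.** The generator reproduces
stage-dependent spectral signatures, sleep architecture, and a two-group
cohort structure with an injectable exposure effect. It does not model
biophysics, electrode artifacts (ECG bleed, sweat drift, movement), subject
heterogeneity in spectral signatures, or the graded transitions of real
sleep. Consequently, classifier accuracies on synthetic cohorts (late-90s
percent) are an upper bound that demonstrates pipeline correctness, not an
estimate of real-data performance, where epoch-boundary ambiguity and
artifacts dominate the error budget.

### Group effects

`group_effect()` shifts the exposed group's generative parameters: N3 and
N2 mean bouts (epochs), SOL mean (minutes), and a sleep-efficiency target
(percentage points, implemented by shrinking the SOL mean and wake dwell by
the factor that removes the requested share of expected non-sleep time —
computed in closed form from the embedded chain). `effect_for_n3_shift()`
converts a target N3-percentage shift into the equivalent bout-length
shift. For effect-recovery studies the package uses a shift of 1.3
night-SDs of N3% (≈ 5.3 points) together with a −4.76 min SOL shift —
the standardized differences implied by the reference study's group
summary table (means 25.46 vs 23.48 with SDs 1.8/1.2 give a standardized
difference near 1.3; SOL means differ by 4.76 min).

## Preprocessing

Fixed order: resample → band-pass → channel repair → ocular artifact
removal → epoching; each step appends to the recording's processing log.

* **Resampling** to 100 Hz by polyphase FIR (anti-aliasing included);
  upsampling is refused as it adds no information.
* **Band-pass** 0.5–40 Hz, 4th-order Butterworth applied forward–backward
  (zero phase, so K-complex morphology and epoch alignment are preserved).
  Realized response at 100 Hz: −0.4 dB at 10 Hz, > 50 dB attenuation at
  0.1 Hz and 49 Hz.
* **Channel repair** replaces a misaligned channel by a weighted average of
  its neighbours; weights default to inverse distance on standard 10-20
  coordinates and fall back to uniform.
* **Ocular artifacts**: symmetric FastICA (tanh contrast) on the EEG
  channels after PCA whitening restricted to the numerically significant
  subspace; any component whose absolute correlation with an EOG channel
  exceeds 0.8 (configurable) is removed. Because in-sample sources are
  uncorrelated, removal can only decrease per-channel variance, and
  re-running the cleaning is a no-op. The correlation rule is the simplest
  reproducible stand-in for manual component selection.
* **Epoching** cuts whole 30-s windows; a trailing partial window is
  dropped (whole epochs are the scoring unit).

## The 20 per-epoch features

Eight time-domain statistics (min, max, mean, median, SD, variance,
skewness, kurtosis), nine spectral features, and three entropies, in a
fixed order. Two deliberate fidelity choices:

* Skewness and kurtosis use the **1/(N−1)** normalization as printed in the
  reference feature table (so Gaussian noise has K ≈ 3·N/(N−1), not 3);
  the conventional 1/N estimator is available via
  `feature_config(moment_norm = "n")`.
* Band features are the **mean PSD over the band** (µV²/Hz), reading
  "density" literally; integrated band power is available via
  `band_mode = "power"`. The K-complex band is 0–1.5 Hz of the computed
  PSD as printed, although the 0.5 Hz filter edge attenuates its lower
  half; likewise γ runs to the 40 Hz filter edge.

The PSD is a Welch estimate: 4-s Hann segments, 50% overlap (0.25 Hz
resolution at 100 Hz), one-sided density scaling — standard practice for
30-s sleep epochs; the estimator is configurable. The spectral centroid
fc, spread fσ, and the PSD interpolated at fc (pfc) are computed over
0–40 Hz; an all-zero epoch returns zeros with a degeneracy flag.

Entropy parameters follow the reference configuration: fuzzy entropy
(m = 2, n = 2, r = 0.3 SD), sample entropy (m = 2, r = 0.2 SD), and
single-scale multiscale entropy (τ = 11, m = 2, r = 0.15 SD). Three
conventions worth noting:

* Sample entropy counts both template lengths over the N−m templates,
  excludes self-matches, and returns the finite-sample cap
  −ln(2/((N−m−1)(N−m))) when no (m+1)-match exists, avoiding infinities in
  feature matrices.
* Multiscale entropy anchors r to the **original** series' SD (the usual
  multiscale convention), then coarse-grains by non-overlapping means of
  τ = 11 samples.
* Fuzzy entropy uses the exponential membership exp(−d^n/r) on mean-centred
  templates. With n = 2 this membership is *not* amplitude-scale invariant
  even for SD-proportional r (the exponent carries one net power of the
  amplitude); SampEN and MSES are scale-free, FUEN is not. The
  implementation follows the printed membership; the scale sensitivity is
  documented rather than silently "fixed", and features are z-scored before
  classification anyway.

The entropy kernels are compiled (Rcpp); unit tests pin them to naive
double-loop reference implementations at 1e−12 on dozens of random inputs.

## Feature selection and staging

A CART tree (Gini impurity, grown deep, no pruning) ranks features by the
total impurity decrease of the **primary splits** they own. Surrogate
splits are deliberately not credited: with surrogates, a duplicated column
would double the pair's combined importance, whereas primary-split credit
makes duplicates share it — the behaviour expected of a redundancy-aware
ranking. The top k = 8 features feed the classifier, mirroring the
reference selection of 8 of 20 features.

Staging uses five one-vs-rest binary SVMs (RBF kernel, C = 1,
γ = 1/k on z-scored features, inverse-frequency class weights to counter
N2 dominance) with Platt-calibrated probabilities; an epoch is assigned the
stage with the maximum calibrated probability, ties breaking to the earlier
stage in the fixed N0–REM order for determinism. The kernel and
hyperparameters are standard defaults — the reference work does not state
its own — and are exposed as arguments.

Cross-validation is **subject-grouped**: subjects, never epochs, are
partitioned into folds, and the ranking, subset, standardization and
calibration are re-fit inside each training fold. A test corrupts one
held-out subject's features and verifies that co-fold subjects' predictions
do not move — the no-leakage property. The reported quantity is epoch-level
mean ± SD accuracy over folds plus per-stage recall and a confusion matrix,
covering both common readings of "average accuracy". Fold counts are
parameterized because the reference description (ten folds of eight
subjects) does not match any fixed cohort size.

No temporal smoothing is applied to predicted hypnograms (the reference
pipeline describes none).

## Hypnogram metrics

TST (h) sums non-wake epochs; stage percentages are fractions of TST; SE =
TST/TSC × 100 with TSC the 9-h collection window; SOL is lights-off to the
first N2 epoch (minutes); RL is first N1 to first REM (hours), with RL% =
RL/TST × 100 reported separately from RL because the reference table
prints values consistent with hours under a "%" heading. The awakening
count WN — undefined in the reference — is the number of maximal interior
wake bouts strictly after sleep onset and before the last non-wake epoch,
matching the clinical sense of "awakening"; leading and trailing wake do
not count. Degenerate staged nights (no N2, or TST = 0) yield NA metrics
with a warning rather than an error, so one bad night cannot abort a
cohort analysis.

## Cohort statistics

Group comparisons use the independent two-sample t-test (pooled variance
by default, Welch optional — the reference's "Sample's t-test" is
ambiguous), a paired t-test for method-agreement comparisons, and 1000-run
within-group percentile bootstrap CIs, all at α = 0.05 with no
multiple-testing correction by default (Holm optional). Degenerate inputs
return sentinels (t = 0/p = 1 for identical constants; signed infinite t
with p = 0 for a constant non-zero paired difference) instead of errors.

The difference column is **sham − exposed**, stated explicitly because the
reference table's sign convention is internally inconsistent; its
formatting convention (percentage-metric differences printed as 3-dp
proportions) is reproduced in `format_comparison_table()`. Relative
changes are computed against the sham mean with an explicit direction
argument.

Calibration facts established by the test suite at the default study
conditions: the per-metric false-positive rate of the full
simulate-measure-compare pipeline under the null generator is ≈ 5% (the
calibration check uses the six continuous, always-defined metrics; WN is a
small discrete count on which a t-test is only approximate, and RL can be
undefined on occasional nights, which would vary the per-replicate n); the
injected standardized N3 effect at n = 21 vs 20 is detected with the
correct sign in well over 80% of replicates; and the percentile bootstrap
CI covers a known mean difference at ≈ 93–95% for Gaussian cohorts of 50
per group — the mild undercoverage at small n is the known finite-sample
behaviour of percentile intervals.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: one-hour nights (120 epochs) for staging
studies — with a 5 ± 2 min SOL so the short night is dominated by scored
sleep — full 9-h nights for metrics-only cohort studies, 50 replicates for
power checks and 200 for calibration checks. Every stochastic step takes
an explicit seed; per-subject seeds are derived from the master seed, and
identical (seed, parameters) reproduce identical hypnograms, signals,
models and reports.

## Known limitations

* The generator's architecture parameters are plumbing calibrated to
  produce summary ranges like those of the reference cohort; no claim is
  made that the bout model is a physiological model of sleep.
* N1-vs-REM separation in synthetic EEG rests on amplitude and β-content
  differences; both are mixed-θ stages, and the single-channel classifier
  would not resolve them on real data without EOG/EMG features.
* EDF I/O is not provided; recordings enter as numeric matrices (or via
  the synthesizer) and hypnograms, features, metrics and comparisons
  round-trip through CSV.
* FUEN's printed membership makes it amplitude-sensitive (see above);
  comparisons across recordings of very different gain should rely on the
  scale-free entropies or re-gauge the signal first.
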