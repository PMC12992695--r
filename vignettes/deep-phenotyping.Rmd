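---
title: "Deep neurobehavioral phenotyping of locomotor states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep neurobehavioral phenotyping of locomotor states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinsonian gait deficits are episodic: normal gait is interrupted by
akinetic episodes (rodent models) or freezing of gait (patients). Because
these interruptions are precisely the *absence* of stepping, gait-cycle
based analysis cannot describe them. `phenogait` instead converts
synchronized kinematic and neural recordings into *continuous* feature
time series on a rolling window, so every locomotor state — gait,
stationary (non-locomotor) movement, and akinesia — is represented at
every time point. Machine-learning models over those features then
(i) decode the state and (ii) rank which neural features carry the
state information, the candidates being biomarkers for closed-loop
stimulation.

## Feature extraction

**Kinematics.** Marker trajectories (mm, 200 Hz rodent / 100 Hz human)
yield per-frame features with a 2-frame window and a 1-frame hop, so the
feature rate equals the frame rate. Speed is the first-difference
displacement magnitude scaled by the frame rate; acceleration the
second-difference magnitude; joint angles use the arccosine of the
normalized dot product of the two limb vectors at the middle marker,
with first and second derivatives; toe height is the z coordinate, and
forward movement is the per-frame displacement along the runway axis,
sign-normalized so that the direction of travel is positive. Derivative
features are back-filled at the first frame(s) so feature length equals
frame count. Gaps up to 10 frames are linearly interpolated; markers
with longer gaps are dropped for that run (mirroring a
fraction-of-valid-points rule applied per marker).

The bundled rodent skeleton (`rodent_skeleton()`) is one consistent
reading of the bilateral hindlimb marker set: per side, speed and
acceleration for hip/knee/ankle/toe, three joint angles with two
derivatives each, and toe height — 36 features. The exact composition of
the original 36-feature panel is not uniquely determined by its
description; the engine is configuration-driven (`skeleton_config()`),
and the fixture documents this package's reading without claiming to
reproduce the original enumeration.

**Neural signals.** Each channel is decimated to 1000 Hz with an
anti-alias filter (all analysis bands lie below 100 Hz), then features
are computed on a trailing (causal) 1-s estimation window at the
kinematic feature rate: the three Hjorth parameters
(activity = variance; mobility = sqrt(var(Δx)/var(x)), a discrete
mean-frequency measure; complexity = mobility(Δx)/mobility(x), the
deviation from a pure sinusoid, exactly 1 for a sine), log band
amplitudes from a Hann-windowed periodogram for the high-beta/low-gamma
band (HB–LG, 20–42 Hz, the established pathological band in
hemiparkinsonian rats) and gamma (60–90 Hz; the rodent gamma band is a
package default, configurable), and band burst rate/duration from the
band-filtered analytic envelope thresholded at the run-level 75th
percentile (both threshold and percentile are package conventions, the
literature being silent). The 1-s estimation window matches the
embedding model's receptive field; it is configurable. State-specific
spectra use Welch's method (0.5-s Hann segments, 50% overlap) on the
first 1.5 s of each state occurrence; shorter occurrences are excluded
and counted.

## Dataset assembly

Runs are concatenated into a multimodal matrix; outliers are set to the
feature median and features are z-scored, with the normalization record
retained so held-out partitions are transformed with training
statistics. Outlier *detection* uses the classical mean/sd z score
(threshold 4): a robust median/MAD criterion was evaluated and rejected,
because state-gated features are strongly bimodal (marker speed is near
zero outside gait; HB–LG amplitude is high only in akinesia), so a MAD
computed from the majority state flags the entire minority state as
outliers and erases the signal the pipeline exists to detect. The
mean/sd rule still replaces isolated spikes (a 50-sigma artifact is far
beyond threshold) while leaving bimodal structure intact. Whether to
z-score per run or globally is an open choice; the package normalizes
globally per training partition, configurable.

Cross-validation is grouped by run (`group_kfold()`): all samples of a
run stay on one side of each split, e.g. 55 runs in 11 folds train on 50
and test on 5 unseen runs.

## Models

**Linear.** `fit_lda()` is Gaussian LDA with a pooled within-class
covariance; when its condition number exceeds 1e8 the covariance is
shrunk toward a scaled identity with the smallest intensity restoring
the bound (recorded in the model). LDA is authored in the package so the
shrinkage intensity, discriminant scalings and shared-covariance
posterior are fully controlled; `MASS::lda` serves as an independent
cross-check in the test suite, where predictions agree. Feature
importance is the mean drop in balanced accuracy over permutations of
one test-partition column at a time. Binary metrics are reported for the
class of interest (gait for the kinematic model, akinesia for the
neural model — the pathological contrast each model is built for), with
macro averages alongside, since a single F1 without a named positive
class is ambiguous.

**Contrastive embedding.** `train_embedding()` learns a temporal
convolutional encoder over the trailing 200 samples (1 s) of the feature
series: a strided first layer downsamples, five stride-1 valid
convolutions reduce the window to one coordinate, GELU activations
(sigmoid approximation) throughout, and the 3-D output is normalized to
the unit sphere. Training minimizes a supervised InfoNCE loss: cosine
similarity over temperature 0.1, positives drawn from samples sharing
the anchor's state label within 200 samples, negatives the other
anchors of the batch (negative sampling is a package decision; the
hidden width, 32, likewise). Optimization is Adam at 5e-4. Two profiles
exist: `"desk"` (batch 128, 2000 iterations), the default used by all
tests, and `"full"` (batch 512, 50 000 iterations) for full-scale runs
on real cohorts. Windows never cross run boundaries; the first
`receptive_field - 1` samples of each run are excluded. Decoding uses a
cosine 3-nearest-neighbor vote with ties broken by the single nearest
neighbor; embedding-space importance permutes one feature column of the
test block *before* embedding and measures the macro-F1 drop.
Gradients are hand-derived and verified against numerical
differentiation in the test suite.

**Joint ranking.** Per-feature importance ranks from the linear and the
embedding model are combined by their maximum (a feature is "consistently
high-scoring" only if both models rank it high); mean-rank combination
is available.

## Statistics

State occupancy differences between groups use independent t-tests per
state with Holm correction. The four-biomarker state contrasts (Hjorth
complexity, Hjorth mobility, HB–LG amplitude, gamma amplitude across
three state pairs) use paired t-tests across subjects, Holm-corrected
over the 12 tests. The human freezing-of-gait contrasts use a
within-session (trial-constrained) permutation test on per-episode
feature means — labels are permuted only within each session stratum,
two-sided p = (1 + #{|T| >= |T_obs|}) / (1 + n_perm) — Bonferroni-corrected
over the 4 features. The test's type-I error calibration and the
uniformity of its null p-values are verified by simulation in the test
suite. Peri-onset curves average feature traces in a ±2 s window around
akinesia onsets (the window extent is a package default; onsets too
close to run edges are excluded and counted; no per-event re-baselining
is applied, matching the default of reporting raw modulation).

## The synthetic cohort

`generate_cohort()` produces the study conditions every test runs under:
8 sham and 6 lesioned subjects, 55 lesioned runs (5 per sham subject),
20-s runs, 200 Hz kinematics and a 1000 Hz two-channel neural signal
(the post-decimation equivalent; emulating the 24.4 kHz acquisition rate
adds nothing to any in-scope computation). State sequences are
alternating semi-Markov chains with exponential dwells truncated to
[0.5 s, run length] — truncation keeps occurrences compatible with the
1.5-s spectral rule — with lesioned akinesia dwell (4 s mean) well above
sham (0.8 s). Gait kinematics are 5 Hz, 15 mm limb oscillations with
per-marker phase lags on a 300 mm/s forward drift; stationary and
akinetic segments are 2 mm and 0.1 mm jitter. Neural channels are pink
(1/f) background plus state-gated band-limited noise: akinesia gates a
20–42 Hz oscillator (amplitude 2.2, left hemisphere emphasized) with a
0.35 broadband admixture; gait gates a 60–90 Hz oscillator (1.8, right
hemisphere emphasized) with 0.5 broadband; transitions are smoothed over
100 ms. The broadband-to-narrowband ratios were calibrated empirically
(the mapping from spectral mix to Hjorth parameters is characterized in
a test, not assumed) so that the generated states reproduce the
documented directions: akinesia has higher HB–LG power and Hjorth
complexity, lower mobility and gamma than gait. A human variant
(`generate_fog_session()`) produces gait/FoG sequences at 100 Hz
kinematics with a 250 Hz six-channel LFP, one channel carrying the
injected FoG modulation (complexity and beta up, mobility down, gamma
up).

What the generator does *not* emulate: artifacts and line noise,
electrode drift, inter-subject anatomical variability, correlated
kinematic-neural noise, and the labeling noise of human annotation.
Passing tests therefore demonstrate that the pipeline recovers effects
it is designed to detect under clean conditions — not that it is robust
to every failure mode of real recordings.

## Numerical choices and limitations

Problem sizes in the tests and the acceptance script are deliberately
modest — a reduced cohort (3+3 subjects, 12-20 s runs) for model fitting and
a compact embedding configuration (receptive field 50, width 16, 300
iterations) for repeated-seed checks — chosen so the whole suite runs on
a single CPU in minutes while every qualitative effect remains
recoverable; the full-scale profile is retained for real use.
Degenerate inputs are first-class: constant signals raise
degenerate-signal errors, zero-length limb vectors name the frame,
constant features are dropped and recorded, session-length mismatches
beyond tolerance produce discard records rather than exceptions, and
single-class strata contribute no permutations. Ties in channel
selection go to the first channel in stable order and are flagged. The
desk-scale embedding does not attempt to reproduce full-scale decoding
scores; its contracts are qualitative (loss decrease, unit-norm output,
above-chance decoding, collapsed manifold under shuffled labels).
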