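---
title: "Methods: simulating, segmenting and classifying fall and ADL events"
author: "fallsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, segmenting and classifying fall and ADL events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsense)
```

## The problem and the measurement model

A chest-worn triaxial accelerometer reports acceleration along three
body-fixed axes in units of g. At rest the sensor reads the gravity vector:
magnitude ≈ 1 g, directed along the longitudinal `z` axis when the wearer is
upright. Events — a fall, a jump, sitting down — appear as short impulsive
bursts (≤ 2 s) riding on this baseline, and posture changes (lying down,
falling) additionally rotate the gravity vector into a new axis. The
pipeline's job is to turn continuous recordings into labelled event windows,
summarise each window with a fixed feature vector, and evaluate how well
standard classifiers separate falls from six activities of daily living
under subject-wise cross-validation.

## The synthetic study generator

`simulate_study()` emulates a 35-subject protocol: each subject performs, in
one continuous 50 Hz recording, 6 ADL events followed by 9 fall events
(steep, and front/left/right/back falls each soft and hard), with rests
drawn uniformly from 5–6 s between events and 2.5 s of rest padding at both
ends. The defaults are the study conditions; `n_subjects`, noise and
variability are exposed on `simulation_config()` but not intended as tuning
dials.

Event waveforms are parametric, one family per event type:

* **Oscillatory bursts** (jumping 4 Hz/3 g, walking 2 Hz/1.8 g, sitting
  2.5 Hz/2 g, standing up 2 Hz/1.8 g): a Gaussian-enveloped cosine on the
  `z` axis with smaller quadrature components on `x` and `y`. The envelope
  and carrier are phased so the designed peak magnitude is reached exactly
  at an on-sample instant — with noise off, a 3 g jumping template peaks at
  exactly 3 g.
* **Posture changes** (lying down 2.2 g, bending 1.6 g): the gravity vector
  rotates smoothly (normalised linear interpolation of the orientation with
  a smoothstep schedule) into the post-event orientation — `+x` for lying
  face down, a transient ~80° tilt-and-return for bending — with a modest
  impact bump at the movement's end.
* **Damped impacts** (falls, 4–6 g): a brief free-fall dip of the gravity
  magnitude, a 9 Hz damped impact oscillation along the landing direction,
  and a rotation into one of four lying orientations (`±x`, `±y`); the fall
  subtypes differ in amplitude (hard > soft > none for the steep fall's
  single variant) and orientation but all carry the class label `Fall`.

After any event that ends away from upright, the subject "stands back up"
over the first 1.5 s of the following rest. One multiplicative amplitude
factor per subject, `exp(N(0, 0.1))`, makes leave-one-subject-out
evaluation non-trivial; i.i.d. Gaussian sensor noise (default σ = 0.03 g) is
added throughout. Per-subject seeds are derived deterministically from the
configuration seed, so the same configuration is bit-reproducible while
subjects differ from one another.

What the generator does *not* emulate: biomechanically realistic fall
dynamics, sensor bias or drift, transmission artefacts, within-subject
variation across repetitions of the same activity, or ambiguous events.
Consequently the synthetic binary task is close to perfectly separable;
passing end-to-end tests demonstrates that the pipeline's plumbing,
segmentation and features preserve the class structure the generator
encodes — it says nothing about accuracy on real recordings.

## Segmentation

Each annotation marks an event's nominal peak time. `segment_recording()`
searches ± 2.5 s (half the minimum rest gap, so windows cannot overlap)
around each annotation for the maximum of the Euclidean magnitude
`sqrt(Fx² + Fy² + Fz²)` — the axis-invariant "sum vector" — and extracts the
inclusive window from 1 s before to 1 s after that peak: `2·fs + 1 = 101`
samples per axis at 50 Hz, with the peak exactly at the centre index. Ties
break to the earliest sample. Events whose peak lies within 1 s of a
recording edge are dropped with a warning rather than padded, because
padding would corrupt every downstream feature statistic.

## Features

24 features per axis, 72 per event, in a fixed interleaved order
(`f1.x, f1.y, f1.z, f2.x, …`; see `feature_names()`):

* **Moment statistics** (6): mean, variance, standard deviation, RMS,
  skewness, kurtosis. All divisors are N (population convention), kurtosis
  is the raw standardised fourth moment (3 under normality), and a
  zero-variance channel defines skewness and kurtosis as 0.
* **Autocorrelation peaks** (3): the biased sample autocorrelation over lags
  0..N−1 (unit value at lag 0) is scanned by iterative tallest-peak
  detection. The exclusion radius around an accepted peak is
  `max(1, round(0.3·T·fs))` lags with the reference period `T = 1/fs`, i.e.
  one lag — a configurable radius, because 30% of one sampling interval
  would otherwise exclude nothing. Lag 0 is admitted and is always the main
  peak, so the informative outputs are the second peak's position (seconds)
  and amplitude. Note that for tones whose period is far from an integer
  number of samples, the tallest non-zero-lag peak can sit at a small
  multiple of the period (the better-aligned lag); position features are
  descriptive, not a period estimator.
* **Spectral peaks** (12) and **band powers** (3): the PSD is estimated by
  Welch's overlapped segment averaging with the classic 8-section geometry —
  section length `floor(N/4.5)` (22 samples at N = 101), 50% overlap,
  periodic Hamming window, one-sided density scaling, no detrending (the DC
  bin carries the mean). The 6 tallest interior local maxima are selected
  iteratively with an exclusion radius of `0.3·fs/N` Hz, floored at one
  grid bin; missing peaks zero-pad the 6 positions + 6 amplitudes so the
  vector length is fixed. Band powers integrate the density over 0.5–5,
  5–10 and 10–20 Hz by the trapezoid rule with interpolated band edges;
  band membership is half-open (`[lo, hi)`) so no bin is counted twice.

The 2-value total-acceleration baseline `[min|a|, max|a|]` supports the
classical magnitude-threshold comparison.

Numerical conventions worth stating: ties in peak amplitude break to the
lower index/frequency; degenerate inputs (zero signal, zero-variance
channel, all-zero PSD) return all-zero feature blocks rather than NaNs; the
Welch estimator requires at least one full section (N ≥ 9 at the default
geometry).

## Classifiers

`model_spec()` + `train_model()` cover kNN (k ∈ {1, 3, 5, 7}), linear SVM,
RBF SVM, LDA and a CART decision tree; SVMs on more than two classes are
automatically wrapped in a one-vs-one ECOC ensemble (`K(K−1)/2` base
models). Choices where the design was genuinely open:

* **SVMs** (`e1071`): cost 1 and RBF width `gamma = 1/d` on standardised
  inputs; no tuning is attempted. An uncalibrated RBF width on a
  60%-majority dataset tends to collapse onto the majority class, which is
  the known failure mode of this family here.
* **kNN**: written in-package for fully deterministic tie handling —
  distance ties resolve to the lowest training index, vote ties to the
  nearest neighbour among the tied classes.
* **LDA**: pooled within-class covariance with a ridge of
  `1e-8 · mean(diag(W))`, and empirical class priors. The ridge exists
  because standardised feature tables legitimately contain all-zero columns
  (a feature constant across the training fold), which a plain pooled
  covariance cannot invert.
* **Decision tree** (`rpart`): Gini impurity, grown until pure
  (`cp = 0, minsplit = 2, minbucket = 1`), empirical priors.
* **ECOC decoding**: pairwise majority vote; ties break by the largest sum
  of signed decision margins over the tied classes, then by the smallest
  class index — fully deterministic even under vote cycles.

## Evaluation and feature selection

`run_loso()` makes one fold per subject (sorted order): the fold's test set
is exactly that subject's events. Features are standardised per fold with
training-fold mean and population SD only (zero-SD features map to 0 in
both sets), so no test information leaks into the transform. Aggregate
accuracy and class-averaged F1 are arithmetic means of the per-fold metrics;
confusion matrices are pooled counts over folds (the convention that
reproduces whole-dataset totals). Per-class F1 is defined as 0 when
precision + recall is 0, and classes absent from a fold's test set are
skipped in that fold's macro average — impossible under the full design,
where every subject performs every event, but defined for partial data.

Decision-tree feature importance follows the branch-node-normalised risk
formula: for each internal node, risk = node probability × Gini impurity,
and the split's contribution is `risk(node) − risk(left) − risk(right)`;
contributions are summed per predictor and divided by the number of branch
nodes. Importances are collected per LOSO fold, averaged, and thresholded
strictly at 0.0002 (`select_features()`). The reference 13-feature subset
(`selected_feature_preset()`) is shipped as a named preset so the reduced
set can be evaluated regardless of what a given selection run returns —
selection on other data, including this package's synthetic data, will
generally pick a different, smaller set, because the simulated waveforms
concentrate their class signal in a handful of orientation features.

## Problem sizes and runtime

The package's own test suite exercises the full 35-subject design (525
events) for the structural counts and the end-to-end separability property
(binary macro-F1 ≥ 0.95 under well-separated templates,
`default_templates(fall_scale = 2.5)`), and smaller 6–10-subject studies
for behavioural tests; a complete simulate → segment → extract → LOSO pass
at 35 subjects takes a few seconds on one CPU. Property-style suites
(moment-statistic oracle agreement to 1e-12, Welch power integral within
20% on white noise, permutation-null collapse, planted-feature recovery)
run on generated data under fixed seeds.

## Known limitations

* Synthetic waveforms are stylised; reported synthetic performance is an
  upper bound, not a forecast for real sensors.
* The Welch section geometry at N = 101 gives a coarse 2.27 Hz grid, so
  spectral peak positions are heavily quantised; this mirrors the short
  event windows, not an implementation limit.
* Autocorrelation "period" features inherit integer-lag quantisation (see
  above).
* No unsupervised event detection: segmentation requires annotations, as in
  the video-validated protocol the pipeline models.
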