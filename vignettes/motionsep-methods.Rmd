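---
title: "Classification-based separation of movement-pattern groups: models and design"
author: "motionsep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification-based separation of movement-pattern groups: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionsep)
```

## The reverse approach

In a virtual-reality embodiment experiment, young participants are randomly
assigned a young (group 0, age-congruent control) or an old (group 1) avatar
and perform upper-body movement tasks while their hand positions are tracked
in two linked coordinate frames: *global* (laboratory) coordinates and
*local* coordinates relative to a height-dependent body reference point.
Classical feature-wise significance testing examines one summary statistic at
a time and misses multivariate structure. The *reverse* approach implemented
here turns the question around: train a classifier to predict the avatar
condition from held-out movement data, and read the out-of-sample accuracy as
the measure of group separation. If the groups cannot be told apart above
chance, there is no evidence of a behavioural difference; if an independent
test set (or an entirely independent second study) is classified well above
chance, the difference is real and its structure can be interrogated through
the classifier.

Two ideas make this work at small sample sizes:

1. **Random window slicing.** Instead of classifying whole sessions
   (n = 72), many fixed-length segments are drawn at random start indices —
   with overlap allowed — from every subject (30 per subject), multiplying
   the training set to 1800 items. Because segments are drawn at random,
   success does not depend on any particular task phase.
2. **Per-subject majority voting.** Each test subject receives 30 segment
   predictions; the subject's label is the modal prediction. Ties (possible
   with an even segment count) are resolved by the sign of the subject's
   mean real-valued decision score when the classifier provides one, and by
   a seeded fair coin otherwise — deterministic given a seed, and using all
   available evidence.

## Classifier families

Five families cover the interpretability-flexibility range. The classical
four consume per-segment (or per-session) feature vectors; the convolutional
network consumes raw standardized segments.

* **LDA** — the Gaussian equal-covariance decision rule: assign x to class 1
  when $x'\Sigma^{-1}(\mu_1-\mu_0) > \tfrac12(\mu_1+\mu_0)'\Sigma^{-1}
  (\mu_1-\mu_0) - \log(P_1/P_0)$, with arithmetic class means, pooled
  within-class covariance (unbiased, divisor n−2) and empirical priors. A
  ridge term $10^{-6}\,\mathrm{tr}(\Sigma)/p$ keeps near-singular problems
  solvable (whole-session runs fit 24 features on 60 subjects). Boundary
  ties go to class 0.
* **SVM** — the soft-margin program $\min \tfrac12\lVert\beta\rVert^2 +
  C\sum_i \xi_i$ s.t. $y_i(x_i'\beta+\beta_0)\ge 1-\xi_i$, classes coded
  ±1, with linear and radial kernels, C = 1 and
  $\gamma = 1/(p\,\mathrm{Var}(X))$ (pooled population variance of all
  feature entries). The optimization is delegated to libsvm via e1071; the
  returned model is verified against the Karush-Kuhn-Tucker pattern and the
  margin identity $M = 1/\lVert\beta\rVert$ rather than re-derived.
* **Random forest** — 1000 trees on bootstrap resamples,
  $r = \mathrm{round}(\sqrt p)$ split candidates per node (5 at p = 24),
  majority vote over trees (the randomForest package).
* **Feedforward network** — two 100-neuron ReLU layers and a two-neuron
  softmax output, Adam, categorical cross-entropy, 10 epochs, learning rate
  0.01, batch size 32 (batch size is unspecified upstream; 32 is the common
  library default and is configurable). Implemented in base R with exact
  backpropagation.
* **Convolutional network** — conv(70 filters, kernel
  $F_1 = \lfloor W/2\rfloor$, ReLU, constant initial bias 0.1) → max-pool
  (window 3, stride 2) → conv(70, $F_2 = 10$, ReLU) → flatten → dense(100,
  tanh) → dense(2, softmax); truncated-normal initialisation (SD 0.05,
  truncation ±2 SD), Adam with learning rate $10^{-4}$, 10 epochs. The
  convolution is the valid cross-correlation
  $(K*S)(i)=\sum_c\sum_{u\le F} K(u,c)\,S(i+u-1,c)$, $1\le i\le W-F+1$,
  and both it and the pooling operator are property-tested against
  brute-force loop oracles. The initialisation SD/truncation and the bias
  constant are not pinned down by any published configuration we follow;
  the chosen values are standard and configurable.

## Evaluation protocols

**Whole-session.** Per run: a balanced test set (6 subjects per class) is
drawn; training and test sides are standardized *separately* (per channel,
pooled over subjects and time, population SD); features are either the four
basic statistics (mean, SD, min, max) per channel of the standardized
profiles, or four principal-component scores per channel. The per-channel
PCA treats subjects as observations and time points as variables, is fitted
on the *unstandardized training profiles only* (centering, no scaling), and
test profiles are projected into the training space. Correct classifications
out of 12 are recorded over repeated runs.

**Segmental.** Per run, after the balanced split, an inner 5-fold
cross-validation on the 60 training subjects selects the window length from
the grid [50, 200, 350, 500, 650]. Design choices where the protocol was
genuinely open: inner folds partition *subjects* (segment-level folds would
leak within-subject correlation) and are stratified by class; the selection
criterion is majority-vote subject accuracy (not segment accuracy), because
the vote is the quantity that matters downstream; ties prefer the smallest
window. The final model is trained on 30 fresh segments per training
subject at the chosen window and evaluated by majority vote over
12 × 30 = 360 test segments. Both test and training segments are redrawn
every run. Degenerate inner folds (possible only for very small synthetic
datasets) are skipped rather than crashing the run.

**Reduced input.** The segmental protocol restricted to the global and
local vertical channels of one hand (8 features), quantifying how much of
the separation the two vertical-position channels alone carry.

**Transfer.** All subjects of one study train; all subjects of the second
study test; no split, so run-to-run variation comes only from segment
redraws. The window is fixed at 200 *time points* and deliberately not
rescaled between sampling rates (20 s at 10 Hz vs 200 s at 1 Hz):
windows are index-based throughout the package. Training uses right-hand
channels; each validation subject contributes the hand matching their
handedness, applied as a channel filter before standardization.
Standardization is fitted separately per dataset. Networks are refitted in
every run, consistent with the redrawn training segments.

**Interpretation.** A linear SVM (C = 1) on the two per-subject features
(mean global y, mean local y) over all subjects at once — no split, no
segments — yields a decision line, margin and support set. On data with the
planted effect the line separates the groups chiefly along the local
(height-relative) vertical axis: at a given global hand height, control
subjects hold their hands higher relative to their own body.

## The synthetic generator

Every stage is testable without tracked recordings through a generator whose
defaults define the emulated study conditions:

* Each local axis is a moving-average-smoothed Gaussian process
  (correlation length `smoothness` = 30 time points, i.e. 3 s at 10 Hz —
  a plausible scale for guided arm movements), SD 1, plus a per-subject
  constant offset (SD 0.15, the between-subject variability of mean
  posture) and white observation noise (SD 0.1). The intercept SD is
  calibrated so that the default one-pooled-SD group effect places
  subject-level separability in the regime the segmental protocols are
  designed to detect (standardized subject-level separation ≈ 4).
* The global axis equals the local axis plus a per-subject offset: for the
  vertical axis an affine function of height, `c0 + c1·height` with
  c0 = 0, c1 = 5 and heights ~ N(1.75 m, 0.09 m), producing the
  characteristic unit-slope scatter of mean global vs mean local y; for the
  horizontal axes a constant stance offset (SD 0.3).
* The group effect is a shift of `effectDelta` pooled channel SDs in the
  mean of the local vertical channel (group 0 higher), the feature the
  two-dimensional boundary analysis identifies. `effectDelta` is expressed
  in units of the pooled (over subjects and time) channel SD — the same
  scale the standardization step divides by. A configuration hook
  (`effectChannels`) can plant effects elsewhere for robustness studies.
* Study-1 mode: fixed length (4970 points at 10 Hz); study-2 mode:
  per-subject lengths uniform on [621, 1361] at 1 Hz with a 4/43 fraction
  of left-handed subjects.

What the generator does **not** emulate: task phases and their ordering,
biomechanical constraints, non-stationarity, head channels, rotations, and
any realistic autocorrelation structure of tracked human movement beyond the
single smoothness scale. Passing tests on synthetic data therefore
demonstrate that the pipeline recovers the *kind* of effect the analysis
targets (a sustained shift in relative vertical hand position) at realistic
sample sizes — not that it would reach any particular accuracy on real
recordings.

## Numerical conventions and edge cases

* Population SD (divisor N) everywhere: basic features, standardization,
  PCA eigenvalue bookkeeping.
* Standardization is per channel by default; a `scope = "global"` variant
  (one pooled scalar pair) exists because the upstream description of
  "the overall mean" is ambiguous between the two readings.
* Time indices are 0-based in segment bookkeeping; windows are half-open
  `[start, start + W)`.
* PCA loadings are sign-fixed (largest-magnitude entry positive) for
  reproducibility; `k` must satisfy `k ≤ min(n − 1, T)`.
* Zero-variance channels, single-class training sets, too-short profiles,
  and window/kernel shape conflicts raise immediate, named errors.
* One master seed per entry point spawns all per-run, per-fold and
  per-subject seeds deterministically; reports embed the per-run seeds, and
  identical invocations are byte-identical.

## Problem sizes used by the shipped checks

The packaged statistical checks emulate the study at 35 + 37 subjects and
T = 1000 time points with the full window grid: 30 runs for the null
calibration, 10 runs for effect recovery, and 10 transfer runs against a
43-subject variable-length validation set. These sizes give stable
qualitative behaviour while keeping the whole suite fast; the protocols
themselves accept the full-scale shapes (T = 4970, 100 runs) unchanged.

## Known limitations

* Under the null, the mean correct count over repeated splits of **one**
  cohort is not exactly binomial around chance: a fixed cohort can carry
  chance group differences shared between the train and test subsets of
  every split, so the 30-run mean scatters around 6/12 with a
  cohort-level component (about ±1.4 at 95% for the default null
  configuration). This is a property of split-based evaluation on a fixed
  cohort, not of the implementation; the cross-study transfer protocol is
  the designed answer to it.
* The feedforward and convolutional networks are exact but plain R; they
  are sized for the study-scale problems here, not for GPU-scale data.
* Non-overlapping segmentation is not implemented; majority voting assumes
  at least one prediction per subject.
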