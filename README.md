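# motionsep

Classification-based separation of movement-pattern groups from
virtual-reality motion tracking.

## The problem

In VR embodiment experiments, participants are randomly assigned a young
(control, group 0) or an old (group 1) avatar and perform upper-body
movement tasks while the positions of their hands are tracked in two
coordinate frames: *global* (laboratory) x/y/z and *local* x/y/z relative
to a height-dependent body reference point — 6 channels per hand, sampled
as long multichannel time series. The scientific question is whether the
avatar condition changes how people move. Feature-wise significance tests
examine one summary statistic at a time and routinely come up empty on such
data; `motionsep` implements the *reverse* approach: train supervised
classifiers to predict the avatar condition from held-out movement data and
read out-of-sample accuracy as the measure of group separation.

The package is for researchers analysing kinematic time series of two
experimental groups — in VR/embodiment work or any setting with a handful
of subjects, long multichannel recordings, and a suspected distributed
behavioural difference.

## The method

For subjects i with feature vectors $x_i \in \mathbb{R}^p$ and labels
$y_i \in \{0, 1\}$:

* **Random window slicing.** m = 30 segments of length W are drawn per
  subject at uniform random start indices (overlap allowed), turning 60
  training subjects into 1800 training items and 12 test subjects into 360
  test segments.
* **Per-subject majority voting.** Each test subject's label is the modal
  prediction over their 30 segments; ties resolve by the sign of the mean
  decision score.
* **Five classifier families.** The Gaussian LDA rule
  $x'\Sigma^{-1}(\mu_1-\mu_0) > \tfrac12(\mu_1+\mu_0)'\Sigma^{-1}
  (\mu_1-\mu_0) - \log(P_1/P_0)$; soft-margin SVMs (linear and RBF kernel,
  C = 1, $\gamma = 1/(p\,\mathrm{Var}(X))$) with margin
  $M = 1/\lVert\beta\rVert$; a 1000-tree random forest with
  $r=\mathrm{round}(\sqrt p)$ split candidates; a 2×100-neuron ReLU
  feedforward network; and a 1-D convolutional network
  (conv(70, $F_1{=}\lfloor W/2\rfloor$) → maxpool(3, 2) → conv(70, 10) →
  dense(100, tanh) → softmax) on raw standardized segments.
* **Subject-wise nested evaluation.** Balanced 6 + 6 test splits, separate
  train/test standardization, inner 5-fold subject-level cross-validation
  selecting W from [50, 200, 350, 500, 650], repeated over many runs;
  plus a cross-study transfer protocol (fixed 200-point windows, no
  resampling across sampling rates) and a two-feature linear SVM boundary
  on (mean global y, mean local y) that makes the separation
  interpretable.

A synthetic trajectory generator with a configurable group effect in mean
local vertical position stands in for tracked recordings, so the whole
pipeline is testable and reproducible offline. See
`vignettes/motionsep-methods.Rmd` for the models, design decisions and
limitations.

## Worked example

```r
library(motionsep)

cfg <- syntheticConfig(nGroup0 = 35, nGroup1 = 37, T = 1000,
                       effectDelta = 1, seed = 42)
ds <- generateDataset(cfg)
ds
#> MovementDataset: 72 profiles
#>   groups: 35 x 0, 37 x 1
#>   channels (6): global_x_right, global_y_right, global_z_right,
#>                 local_x_right, local_y_right, local_z_right
#>   time points: 1000

rep <- runSegmental(ds, methods = "SVM_LIN", nRuns = 10, seed = 7)
rep
#> EvaluationReport: 10 runs x 1 method(s)
#>   SVM_LIN  mean correct 11.60 / 12
correctHistogram(rep, "SVM_LIN")
#>  0  1  2  3  4  5  6  7  8  9 10 11 12
#>  0  0  0  0  0  0  0  0  0  0  0  4  6

fitBoundary(ds)
#> DecisionBoundary2D: -0.9826 * mean_global_y + -2.7595 * mean_local_y
#>   + 10.4539 = 0 (margin 0.3414)
```

A one-pooled-SD upward shift of the control group's mean local vertical
position drives the segmental linear SVM to 11–12 correct test subjects out
of 12 in every run (mean 11.60), while the same pipeline sits at chance
(≈ 6/12) when `effectDelta = 0`. The fitted two-feature boundary has a
negative `mean_local_y` weight: among subjects with the same global hand
height, those holding their hands *lower relative to their own body* are
assigned to the old-avatar class — the interpretable signature of the
planted (and, in the motivating experiments, observed) effect.

A thin command-line wrapper covers the same workflow
(`inst/scripts/motionsep.R`):

```sh
Rscript inst/scripts/motionsep.R simulate --n0 35 --n1 37 --T 1000 \
    --seed 1 --out data/
Rscript inst/scripts/motionsep.R evaluate --data data/manifest.csv \
    --mode segmental --methods SVM_LIN --runs 10 --seed 1 --out report.json
```

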