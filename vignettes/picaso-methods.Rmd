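---
title: "Cascaded attentional set operators for histopathology instance sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded attentional set operators for histopathology instance sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picaso)
```

## The problem

A renal biopsy yields a *set* of glomerular image crops per case — a handful
to dozens, in no meaningful order. Clinically relevant questions attach
either to a single instance inside the set (which glomerulus carries an
active crescent, the C-lesion of the Oxford Classification of IgA
nephropathy) or to the case as a whole (is a kidney-transplant biopsy
antibody-mediated rejection or not). Any model for such data must be a
*valid set operator*: it has to accept a variable number of instances M and
return the same answer for every ordering of them.

`picaso` implements a cascaded attentional set operator together with the
standard baselines (DeepSet pooling variants, Set Transformer), the two task
heads, group-aware experiment construction and an evaluation harness, all
exercisable end to end on synthetic data.

## The operator

Let $E_n \in \mathbb{R}^{M \times d}$ hold the embeddings of the $M$
instances of case $n$. The operator maintains a small matrix of
*histopathologic vectors* (HiVe) $\mu \in \mathbb{R}^{N_{HV} \times d}$. The
initial $\mu_0$ is a trainable parameter, drawn at initialisation from the
Kaiming scheme (zero mean, variance $2/d$); it acts as a static memory of
what the task's discriminative features look like. A cascade of $J$
Transformer blocks then updates it against the current input set:

$$\mu_{j+1} = \mathrm{Transformer}(\mu_j,\; E_n,\; E_n), \qquad j = 0, \dots, J-1,$$

with $\mu_j$ as the query and $E_n$ as key and value. Each block is
multihead scaled-dot-product cross-attention ($N_h$ heads, scores scaled by
$1/\sqrt{d/N_h}$) followed by a feed-forward sublayer. Because the instances
enter only through row-wise softmax weights and weighted sums, every block —
and therefore the whole cascade — is permutation invariant and accepts any
$M \ge 1$. The attention scores per step form an $N_{HV} \times M$ matrix
per head, so compute and memory grow linearly in $M$ (there is no
$M \times M$ structure anywhere in the cascade; `picaso_aggregate()` counts
the materialised score entries so this is testable rather than folklore).
Block parameters are shared across the $J$ steps by default, so the
trainable parameter count does not grow with the cascade depth; `n_params()`
makes that checkable in one line.

Two compositional details are deliberate choices where the operator's
definition leaves room:

* **Block composition.** Pre-normalisation with residual connections around
  both the attention and the feed-forward sublayer, feed-forward width $2d$
  with a GELU nonlinearity. Pre-norm is the stable modern default for short
  cascades; the width multiplier is exposed in `aggregator_config()`.
* **Constant width.** The HiVe keeps the same width $d$ at every step.

## The K-means view

Strip the block to its skeleton — identity query/key/value projections, no
feed-forward, no residual — and score instance $i$ against centroid $k$ by
$-\lVert x_i - \mu_k \rVert^2 / \tau$. The softmax over $k$ then gives soft
assignments, and the update replaces each centroid by its assignment-weighted
mean. As the temperature $\tau \to 0^+$ the softmax hardens into
nearest-centroid assignment and the update is exactly one Lloyd step of
K-means; as $\tau \to \infty$ every centroid collapses onto the global mean.
`kmeans_limit_update()` implements this pathway (a dot-product score variant
is also provided; the distance score is the one whose zero-temperature limit
is exactly Lloyd). A centroid whose total soft assignment underflows to
numerical zero keeps its previous value, which coincides with the usual
Lloyd convention for empty clusters. The tests verify the Lloyd equivalence
against a brute-force oracle at $\tau = 10^{-6}$ and recover planted
mixtures at ten-sigma separation with adjusted Rand index above 0.95.

## Heads

* **Instance anomaly head** (one-positive task, requires $N_{HV} = 1$). The
  final HiVe is an attention-weighted mean of the instance embeddings, so a
  lesion-carrying instance betrays itself by distance from it. The head
  computes $|E_i - \mu|$ elementwise, feeds the $d$-vector of absolute
  differences through a shared affine layer into one logit per instance, and
  a sigmoid. The operator's definition would equally admit feeding the
  scalar L1 distance itself; the vector form subsumes it (uniform weights
  recover the scalar behaviour) and is the default, with
  `head_mode = "scalar"` available. Training uses independent per-instance
  sigmoid + binary cross entropy against the one-hot target — not a
  softmax over the set — matching the stated loss.
* **Set head** (binary task). Flatten the final HiVe, one affine layer, a
  sigmoid. The decision threshold is 0.5 with ties classified positive.

## Experiment construction

Sets are built by Monte Carlo sampling from an instance pool, as in the
underlying study design: for the one-positive task, $m \sim U\{3..7\}$
lesion-free instances from one case plus one lesion instance (total size
4–8); for the binary task, $m \sim U\{4..8\}$ instances of one case with the
case's label. $m$ is drawn uniformly — the design says only that the set
size varies per iteration, and uniform is the maximum-entropy default.
Negatives default to the positive's own group (the per-WSI scheme), with a
mixed-group option for harder variants. When a group is too small, online
augmentation (random resized crop, vertical flip with probability 0.5,
rotation up to ±30°) fills the set; augmented members are flagged and carry
their own seeds so evaluation can exclude or reproduce them. Exact
augmentation parameter ranges are not pinned down by the design; the
defaults above are stated in `augment_instance()` and configurable.

Cross-validation folds are group-aware: groups (WSIs/cases) are assigned
largest-first to the lightest of k folds, so no group ever straddles
training and validation and every group is validated exactly once. Crop
preprocessing masks pixels outside the glomerulus, zero-pads to a square
(centred — the design is silent on placement) and resizes isotropically, so
the foreground aspect ratio is preserved.

## Synthetic data: what it emulates and what it does not

The clinical image sets are not redistributable, so the package ships two
generators whose statistical structure mirrors what the experiments assume:

* `gen_mixture_sets()`: per set, k cluster means on a sphere of radius
  (separation × within-cluster SD), isotropic Gaussian points, ground-truth
  assignments returned. Defaults (k = 3, 8 dimensions, 20 sets) are declared
  package defaults for the clustering experiment, not a reproduction of any
  published configuration.
* `gen_lesion_image_sets()`: each instance is a noisy ellipse
  ("glomerulus") on a darker background; a positive instance additionally
  carries a crescent-shaped annular arc subtending 90–180° hugging the
  ellipse boundary at a stated additive contrast. Cases are assigned
  round-robin to ≥ 2 cohorts standing in for institutions; each cohort adds
  a global brightness offset plus a mild per-channel tint, the minimal
  controllable analogue of stain/scanner differences. The binary task plants
  the motif with elevated prevalence (`p_pos = 0.6` vs `p_neg = 0.05`) in
  positive cases.

Defaults are the package's study conditions: 200 cases, 64×64 RGB images,
contrast 0.6 against pixel noise SD 0.05 (a clearly separable regime),
brightness shifts (0, +0.08, −0.06), 7 negatives + 1 positive per case, and
10 Monte Carlo sets per case per training run — the last mirrors the
original design's many set draws per slide and is what makes 20 epochs at
learning rate 1e-4 enough optimiser steps to matter. Contrast 0 is the
no-signal null: positives and negatives are then identically distributed
and a trained model must hover at chance.

What passing on this data does **not** show: real glomeruli are not
ellipses, stain variation is not an additive offset, lesions are not always
geometrically crisp, and annotation noise does not exist here. The synthetic
results validate the machinery (invariances, gradients, training dynamics,
evaluation), not clinical performance.

## Training, evaluation, uncertainty

Training is minibatch Adam (default learning rate 1e-4, 20 epochs, 32 sets
per batch) on binary cross entropy; all forward/backward passes are plain
matrix algebra inside the package and are verified against central finite
differences in the test suite. Training aborts with a diagnostic on a
non-finite loss.

Evaluation pools instance scores across validation sets (one-vs-rest
reading) for AUROC — rank-based with midrank ties — and AUPR as tie-grouped
average precision; both are checked against quadratic-time oracles to 1e-9.
Recall for the instance task is reported at two operating points, because
the operating point is otherwise unstated: the argmax convention (fraction
of sets whose true lesion instance receives the top score — the default
`recall`) and instance-level recall at threshold 0.5
(`recall_threshold`). Accuracy uses threshold 0.5, ties positive.

Uncertainty machinery is deliberately distribution-free: percentile
bootstrap over whole sets (default 1000 resamples) for 95% confidence
intervals, and a paired bootstrap of metric differences (10⁴ resamples,
shared resample indices, +1 continuity correction) for two-sided P values,
so identical models compare at exactly P = 1 and P never leaves (0, 1].

Two sweeps complete the harness: `sweep_steps()` retrains across cascade
depths J (performance need not be monotone in J, so nothing asserts that it
is), and `sweep_set_size()` rebuilds evaluation sets at sizes beyond the
training maximum of 8 without retraining — robustness there is the point of
a valid set operator.

## Problem sizes and numerical choices

The shipped test and acceptance runs use 200 cases (≈ 1600 images at 64×64)
with a 5-fold group split, a d = 64 cascade with 8 heads and J = 3, 10
Monte Carlo sets per training case, and a 100-case zero-contrast null at 5
epochs; the set-size sweep evaluates 40 fresh deep-pool cases at
M ∈ {4, 8, 16, 32}. These sizes train in minutes on one CPU core and were
chosen as the smallest configuration in the clearly-separable regime where
the end-to-end properties are stable across seeds.

Permutation invariance is exact in real arithmetic but not in floating
point (summation order changes), hence the 1e-5 tolerance used throughout;
attention rows are checked to lie on the probability simplex to 1e-6. The
encoder is a deliberately small stand-in trained from scratch: fixed 4×
average-pool input reduction, two 3×3 convolution stages (16 and 32
channels) with average pooling, global average pooling and a linear map to
d — enough capacity for planted-motif images while keeping a full study in
CI budgets. Large pretrained backbones plug in through
`encoder_spec("external")` but are intentionally untested here.

## Known limitations

* The two "++" baseline variants are documented simplified stand-ins
  (equivariant pre-aggregation layers added to DeepSet; one extra
  self-attention block for the Set Transformer); fidelity to any particular
  published "++" architecture is a non-goal.
* No positional or spatial information: the operators are purposely
  permutation invariant, so tasks needing spatial correlations between
  instances are out of scope.
* Single-CPU, pure-R training: fine at desk scale, not a route to clinical
  scale.
* Calibration is not addressed; scores support ranking metrics, and the 0.5
  threshold metrics inherit whatever miscalibration training leaves behind.
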