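---
title: "Methods: brain-network features, separable-convolution pruning, and the cascaded multimodal classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurocascade)
```

This vignette explains the models the package implements, the choices
behind their parameters, and what the synthetic experiments do and do
not demonstrate.

## The quantification problem

Alzheimer's disease (AD) and its prodrome, mild cognitive impairment
(MCI), alter both brain function and brain structure. Two complementary
imaging views capture this: resting-state fMRI yields region-level BOLD
time series whose correlations define a functional connectivity network
(FCN), and diffusion imaging yields fractional anisotropy (FA) values
whose region-pair strengths define a structural connectivity network
(DTISCN). The package quantifies cognitive status along two routes:

1. **Connectome route** — graph-theory features of the FCN/DTISCN with
   two-sample t-test selection of discriminative features.
2. **Image route** — a cascaded 3D convolutional classifier over local
   image blocks of paired MRI/PET volumes, with per-location fusion of
   the two modalities, plus occlusion mapping of the discriminative
   regions and channel pruning to control model cost.

## Connectome features

Preprocessed BOLD series have their first 5 volumes removed
(`trim_initial_volumes`); the early scanner signal is not at
steady state. Functional edges are Pearson correlations of region-mean
series over the full retained window; an FCN edge exists where the
correlation exceeds a threshold. No canonical threshold exists, so it
is a configuration parameter defaulting to 0.3 — a mid-range value in
common use; results should be read per threshold, not across them.
Negative correlations are dropped by default (the network is a
nonnegative weighted graph); an absolute-value policy is available.

FA per voxel derives from the diffusion-tensor eigenvalues as
`sqrt(3/2) * sqrt(sum((eta - mean(eta))^2) / sum(eta^2))`, 0 for
isotropic and 1 for maximally anisotropic diffusion. Structural edges
keep region-pair FA values at or above 0.2, the conventional cutoff
below which no reliable fiber is assumed; the companion 35° fiber-angle
rule belongs to tractography, which this package does not perform, and
is carried as metadata only. Absent entries (failed tracking) are
explicit `NA`s.

Per node and network the package computes weighted degree (summed edge
weights), local efficiency (mean inverse shortest-path length over
ordered pairs in the neighbor-induced subgraph, 0 for fewer than two
neighbors, where path length uses the `1/weight` convention so strong
connections are short), and unnormalized betweenness centrality
(fraction of shortest paths passing through the node as an interior
vertex). Betweenness uses igraph's weighted implementation; efficiency
uses an internal Floyd–Warshall on the induced subgraph so the
ordered-pair normalization is exactly the formula above. Both are
verified against exhaustive simple-path enumeration on all graphs up to
8 nodes in the test suite.

Feature vectors concatenate (network, metric, node) in a fixed order —
`3 metrics x 52 regions x 2 networks = 312` features by default — and
selection applies a two-sided Welch t-test per feature, uncorrected at
`alpha = 0.05` by default (an optional Benjamini–Hochberg flag exists).
Uncorrected selection is deliberate: the procedure screens candidate
features rather than asserting familywise error control, and the null
calibration experiment verifies the ~5% false-positive rate directly.

## Cost accounting and channel pruning

A standard convolution over a `D1 x D1 x M` input with `D2 x D2`
kernels and `N` outputs costs `D1^2 D2^2 M N` multiply-adds and
`D2^2 M N` parameters. Its depthwise-separable factorization costs
`D1^2 D2^2 M + M N D1^2`, a ratio of `1/N + 1/D2^2`. The package's
ledger (`schedule_ledger`) prices whole schedules at the
"same-padding, ceiling-division stride" convention; on the frozen
MobileNet-v1 schedule the 1x1 pointwise stages account for ~95% of all
multiply-adds, which is why channel pruning that thins pointwise inputs
is where the cost is.

A separable unit is the triple `<L_i, D_i, P_i>` (input activations,
depthwise 3x3 stage with ReLU, pointwise 1x1 stage). Channel
importance is APoZ — the average fraction of exact zeros in a
channel's post-ReLU depthwise activation over an evaluation set (a
held-out fifth of the training data by default; ReLU emits exact
zeros, so zero detection is equality, not a tolerance). Pruning ratio
`epsilon` removes the `floor(M * epsilon)` highest-APoZ channels per
unit; ties retain the lower channel index. Removing channel `j` of
unit `i` removes the `j`-th depthwise filter, the `j`-th input slice
of every `P_i` filter, and the `j`-th output filter of `P_{i-1}` — so
a unit's own output width `N` never changes, and the pruned unit costs
exactly `(1 - epsilon)` times the original. The first unit's input
channels are never removed (they are the network input's producers).

Pruning is mask-then-materialize: planned weights are zeroed and
frozen (zero learning rate) during fine-tuning, then physically removed.
Masked and materialized networks are forward-equivalent to the exact
floating-point operation — an invariant the tests check over random
(model, plan, input) triples — because the units carry no batch
normalization. That is a documented modeling restriction: with
normalization layers, a zeroed channel would leak a constant offset
and break removal equivalence; folding normalization into weights
before pruning restores it.

Two schedules exist: one-shot ("greedy") pruning of all units followed
by a single fine-tune, and shallow-to-deep layerwise pruning with
fine-tuning between units, which re-measures APoZ as earlier pruning
changes downstream activations.

Training throughout uses softmax cross-entropy (`softmax` is the
standard `e^{+z}` normalized exponential), Adadelta (rho 0.95, eps
1e-6), batch 64, and Xavier uniform initialization.

## The cascaded multimodal classifier

Volumes are mean-downsampled by 2 and cropped to the nonzero bounding
box (`crop_and_downsample`). The package's default working geometry is
25 x 21 x 20 voxels — the full-scale 100 x 81 x 80 enclosing box
scaled down by 4 so that the full pipeline trains in minutes on one
CPU core; the full size remains a configuration away. A 3 x 3 x 3
grid of ~50%-overlapping blocks (27 blocks; count fixed, layout a
design choice since only the count is canonical) covers each volume.

Per (modality, block), a local 3D net — input standardization (voxel
means and a scalar scale estimated from the training fold only), 2x
mean pooling, a 3^3 convolution with ReLU, an 8-unit hidden layer, and
a softmax head — is trained on the shift-augmented training fold. The
augmentation is the 8 corner shifts `(+-2, +-2, +-2)` of each volume,
applied to training data only; "eightfold in all directions" is
realized as the corners of the shift cube. Training runs 20 Adadelta
epochs, the point at which these nets' loss curves flatten.

The intermediate-feature tap is the post-ReLU output of the (single)
convolution layer — the penultimate learned representation before the
fully-connected stage. Per block, the two modalities' 3D tap maps are
folded along depth into channels, stacked channelwise, and fed to a 2D
fusion net (3x3 convolution, hidden layer, softmax) whose hidden
activations are the fused per-location features. A fully-connected
combiner over all 27 locations yields the cascade prediction;
analogous combiners over single-modality features give the
single-modality cascades.

Four reference fusion strategies are implemented for comparison:
probability averaging, feature concatenation, channelwise joining of
last-conv features (via channel-wise spatial averaging), and bilinear
outer products of the per-block feature vectors averaged over blocks.
Evaluation is stratified 10-fold cross-validation with all fitting —
augmentation, normalization statistics, APoZ, every net — strictly
inside training folds; metrics (accuracy, sensitivity, specificity,
AUC) pool the out-of-fold probabilities.

Transfer initialization (`transfer_init`) copies local and fusion nets
between architecturally identical task bundles and re-initializes the
combiner, the protocol for the easy-to-hard chain (AD/NC initializes
pMCI/NC initializes sMCI/NC). The synthetic surrogate for "harder"
tasks is the MCI group, generated at half the AD lesion contrast.

## Occlusion saliency

A gray cube — 15 voxels at full scale, hence 4 at the package's
4x-reduced default geometry — slides over the input with stride 2
(full-scale 5, rescaled and rounded down, trading resolution for a
~9x smaller scan than stride 1); its fill value is the mean intensity
of the input block. The map value per position is the drop in
true-class probability.

The scalar gray fill presumes globally normalized intensities: "gray"
must be a neutral tissue value everywhere. The synthetic volumes are
not normalized — their background has a strong radial gradient — so a
scalar fill is darker than the local background in central regions and
*creates* lesion-like artifacts rather than removing evidence. For
such data the package provides `fill = "reference"`: the cube is
filled with the training-cohort voxel-mean template, which is exactly
the gray (zero) value in the network's standardized input space. The
localization experiment uses this fill; the scalar rule remains the
default and keeps its contract properties (a fill equal to the
underlying intensities leaves the map exactly zero). Negative drops are retained; whether to
normalize across subjects is genuinely open, so aggregation reports
both the raw mean map and a z-scored variant. Block choice for
analysis follows per-block validation accuracy (`top_blocks`, default
3). The localization experiment checks that the aggregate map's argmax
falls inside the planted lesion.

## The synthetic cohorts

The generators produce data with exactly the statistical structure the
analyses assume, nothing more:

* **Time series** — multivariate normal draws from a block-community
  correlation template (4 communities, within-block correlation 0.5,
  between 0.1, additive measurement noise at scale 0.2); group effects
  attenuate correlations incident to the designated effect nodes by
  `0.2 * effect_size` (AD fully, MCI half). With 135 retained
  timepoints this puts single-edge differences near the detection
  boundary while node-level aggregates (degree) are reliably
  recoverable at `effect_size = 1.5`, `n = 30`/group — the reference
  recovery conditions.
* **FA matrices** — a shared sparse backbone (banded neighbors plus 8%
  random long-range edges, baseline FA uniform on [0.3, 0.7]), a
  downward shift of `0.1 * effect_size` on effect-node edges in
  affected groups, symmetric noise, and a 15% per-subject absent-entry
  rate emulating failed tracking.
* **Volume pairs** — a smooth head-like background, spherical lesions
  (radius 3.5 voxels) whose intensity drops by the class contrast 0.5
  in AD (half in MCI), additive voxel noise at scale 0.6, and a 5%
  multiplicative subject gain nuisance. The MRI and PET lesions sit at
  different sites, so each modality carries an independent share of
  the class signal and fusion is genuinely informative. These
  magnitudes were fixed once as a realistic desk-scale operating
  point: per-voxel contrast-to-noise below 1 (single blocks are
  imperfect classifiers) while the multivoxel lesion signal is
  recoverable — the generators' contract is that the pipeline's own
  methods can recover what they plant.

Every generator draws each subject from an RNG stream derived from
(seed, subject index), so enlarging a cohort never perturbs existing
subjects.

**What passing these experiments shows** — that the implementations
are internally correct (oracle equivalence, forward equivalence,
calibrated nulls) and that the pipeline recovers effects of known
location and size from data satisfying its assumptions. **What it does
not show** — anything about real ADNI-scale performance: the synthetic
volumes have no anatomy, registration error, scanner artifacts, or
site effects, the cohorts are small and balanced, and lesions are
spherical and fixed in location.

## Problem sizes and numerical choices

The reference experiments run at deliberately modest sizes: recovery
uses 50 replicates of 30 + 30 subjects; null calibration uses 200
replicates of a reduced cohort (20 regions, 10/group, 60 timepoints),
which estimates the same per-feature type-I rate at a fraction of the
cost; the cascade uses 20 + 20 subjects at 25 x 21 x 20 under 10-fold
CV; the permutation null repeats a scaled-down protocol (single
modality, one whole-volume block, 5 folds) 20 times, since the
leakage-freedom it checks is a property of the harness, not of the
grid size; saliency localization uses 20 independent seeds.

Numerical details worth knowing: probabilities are clamped at `1e-12`
inside the cross-entropy; softmax subtracts the column maximum;
correlation matrices are symmetrized and unit-diagonal by
construction; shortest-path ties are resolved exactly (igraph counts
all shortest paths; the brute-force oracle uses a `1e-9` length
tolerance); the FA threshold comparison is inclusive (`>= 0.2`);
`floor(M * epsilon)` can be zero, making pruning a no-op on small
units; all trainers are deterministic given `(seed, single thread)`.

## Known limitations

* The NN engine is dense, CPU-only, single-threaded R; it is built for
  desk-scale correctness, not throughput.
* No batch normalization (see pruning equivalence above), no
  convolution padding (valid convolutions only), integer-factor
  pooling.
* The per-pixel probability-score + SVM benchmark described alongside
  the original cascade experiments is not implemented; the package's
  baselines are the four fusion strategies.
* Region identity is label metadata; no atlas is shipped, and nothing
  anatomical is implied by node indices.
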