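---
title: "Weighted multi-view 3D convolutional classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multi-view 3D convolutional classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Diagnosing a knee-joint abnormality such as an anterior cruciate ligament
(ACL) tear from MRI is intrinsically a *multi-view* problem: a clinical
exam acquires several orientations and weightings (e.g. T1-sagittal,
T2-sagittal, T2-coronal, T2-transverse), and no single view fully reveals
the three-dimensional morphology of the ligament. `mvfusion` implements a
binary classifier for such data built from three parts:

1. **A shared-weight 3D residual encoder.** Every view volume
   $v \in \mathbb{R}^{D \times H \times W}$ (depth = slices, height,
   width) is mapped by one convolutional network $f$ — the same parameter
   set for all views — to an embedding $h = f(v)$ of fixed length (512 at
   full scale). The network is built from basic residual blocks
   $z = F(v, W) + v$ with $F$ = conv–BN–ReLU–conv–BN and a ReLU after the
   addition; a 1×1×1 projection shortcut is inserted whenever channel
   count or stride changes. A global adaptive average pool makes the
   embedding length independent of the input's spatial size.
2. **Softmax-weighted feature fusion.** A small shared scoring MLP maps
   each view's embedding to a scalar; a softmax across the $n$ views turns
   the scalars into nonnegative weights $a_1,\dots,a_n$ summing to 1.
   Each embedding is scaled by its weight and the scaled embeddings are
   concatenated into a fused feature of length $n \times 512$.
3. **A two-layer classifier head.** The fused feature is mapped to width
   512, passed through a ReLU, and reduced to one logit; a sigmoid yields
   the predicted probability $\hat y$. Training minimises binary
   cross-entropy $L(y,\hat y) = -(y\log\hat y + (1-y)\log(1-\hat y))$
   with Adam.

Three comparison fusion strategies are implemented for the ablation
harness: plain concatenation (unit weights), label-fusion by averaging
per-view probabilities, and label-fusion by softmax-weighted averaging of
per-view probabilities.

## Why the network is hand-built

No deep-learning framework is assumed: forward and backward passes of
every layer (3D convolution via im2col/GEMM in C++, 3D batch
normalisation, max pooling, global average pooling, linear layers, the
softmax weighting mechanism and all four fusion heads) are implemented in
the package and verified against central finite differences in the test
suite. This keeps the package self-contained and makes every computation
inspectable.

## Training recipe

The full-scale reference recipe is Adam with learning rate $10^{-4}$,
first-moment coefficient $\beta_1 = 0.9$ (the "momentum" of the original
recipe, read as Adam's first moment since the optimiser is Adam), weight
decay $10^{-4}$ (implemented as an L2 term added to gradients), batch
size 32 and 100 epochs. After every epoch the validation AUC is computed
in eval mode; the snapshot with the highest validation AUC is kept, ties
resolved toward the earlier epoch. Model selection uses AUC because AUC
is also the evaluation metric.

Desk-scale phantom experiments (below) use the reduced encoder (channels
8/16/32/64, embedding 64), batch size 16, learning rate $2\times10^{-3}$
and weight decay $10^{-3}$: 20 epochs on 70 training cases is only about
100 Adam steps, and at $10^{-4}$ a freshly initialised network barely
moves in that budget, while too-small steps let memorisation of the tiny
training set outrun feature learning.

Degenerate inputs are rejected rather than silently handled: a training
partition with one class is an error, a non-finite loss aborts with a
diagnostic naming the epoch, and AUC is refused when only one class is
present. Probabilities inside the loss are clamped to
$[10^{-7}, 1-10^{-7}]$ so the loss is finite on the closed interval.

## Preprocessing conventions

Clinical volumes arrive with heterogeneous slice counts (15–20 in one
layout, 17–61 in another) and in-plane sizes (512×512 vs 256×256). The
pipeline harmonises each view independently:

* in-plane bilinear resize (half-pixel centres) to the target size;
* per-volume z-score normalisation — the standard answer to MR intensity
  non-uniformity across scanners; population standard deviation is used;
* depth harmonisation by symmetric centre-crop (crop before
  normalisation) or symmetric zero-pad (pad after normalisation, so
  padding sits exactly at the mean), with the asymmetric extra slice at
  the trailing end.

Depth interpolation is deliberately avoided: cropping and padding
preserve slice anatomy. The z-score statistics are computed over non-pad
voxels (leading/trailing all-zero slices are treated as padding), which
makes preprocessing idempotent — a property the test suite asserts. A
constant-intensity volume has no scale and is normalised to all zeros
with a warning, not an error.

Canonical view order is whatever the dataset manifest declares — never
filesystem order. Axis convention is (depth, height, width) throughout.

## The phantom world

Because the clinical datasets are private or gated, every pipeline stage
is exercised on synthetic phantoms whose construction mirrors the
structural challenge of multi-view diagnosis: the class signal is split
across views so that no single view suffices.

Each view's background is an independent smooth low-frequency bias field
(three random cosine components, amplitude $U(0.05, 0.15)$, frequency
$U(0.25, 0.75)$ cycles per extent) plus i.i.d. Gaussian noise
(sd 0.5). A positive case carries an ellipsoidal lesion — smooth profile
$A\,e^{-2\rho^2}$, shared centre and radii across views — but view $v$
renders only the voxels whose azimuth around the lesion centre falls in a
window of width `viewInformativeness[v]`, offset by $(v-1)/n$. The
default width is 0.5: each view sees half of the lesion's angular extent
and the union of the four default views sees all of it, so no view is
fully informative (width $1/n$ gives fully disjoint complementary wedges;
width 1 a fully informative view).

A second knob, `lesionArc`, controls how focal the lesion is. At the
default 1 the lesion is the full ellipsoid. With `lesionArc < 1` the
lesion occupies only a random azimuthal sector per case — a focal tear —
so on one patient a given view may render most of the tear and on another
none of it. This is the regime in which *learned* view weighting can
genuinely help: a fixed per-view scaling is absorbed by the first linear
layer of a concatenation head, so softmax weighting only has an edge when
per-view informativeness varies case by case. It is also the regime that
caps single-view performance structurally (a view whose window misses the
tear's sector cannot detect it) and that penalises probability averaging
(blind views dilute the average). The ablation experiments therefore run
on a sectored, asymmetric-window world; the worked comparisons in the
test suite document the exact parameters.

Defaults were calibrated once, openly, against two criteria the phantom
world is required to satisfy: a trained reduced model should reach test
AUC ≥ 0.9 at desk scale (the world must be large enough for AUC
separation), and an amplitude-0 null world must train to chance. The
default amplitude 1.5 over noise sd 0.5 is the point at which an ideal
matched-filter detector — independent of the network — saturates,
leaving margin for a small CNN trained from scratch. Lesion radii are
$U(0.25, 0.4)$ of each axis extent: much smaller lesions remain
detectable by the matched filter but their globally-average-pooled
activations are too dilute for a small from-scratch CNN trained on 70
cases — a learnability, not detectability, limit.

Datasets are split 70/10/20 (train/validation/test), stratified by label
with `round(positiveFraction × size)` positives per partition, clamped so
both classes appear everywhere. Generation is a pure function of the
spec, including its seed.

**What a green phantom test does and does not establish.** Phantoms share
with real MRI the dimensionality, the multi-view structure, the partial
per-view visibility and the noise-over-background character of the
signal; they do not model anatomy, MR physics, scanner artefacts,
inter-reader label noise or class imbalance. A passing phantom suite
establishes that the machinery — encoding, weighting, fusion, training,
selection, evaluation — is correct and that the method recovers planted
multi-view signal; it says nothing about clinical performance.

## Numerical and design choices

* **Scoring network sharing.** Whether the per-view scoring MLP shares
  parameters across views is unstated in the original description;
  parameters are shared here (one 512→64→1 network applied to each view),
  which keeps the mechanism valid for any number of views and mirrors the
  shared encoder. The hidden width 64 is a free choice.
* **Zero-initialised gate.** The scoring MLP's output layer starts at
  zero, so view weights start exactly uniform and weighted concatenation
  coincides with plain concatenation at step 0. A randomly initialised
  gate injects per-case weight noise into the head and encoder during the
  earliest steps, which measurably destabilises short desk-scale runs.
* **Weights before concatenation.** "Weighted and concatenated" is read
  literally: embeddings are scaled, then concatenated. Scaling blocks
  after concatenation is algebraically identical.
* **Label-weighted fusion weights.** The source of the weights in
  class-probability weighting is unstated; the same learned softmax view
  weights are applied to the per-view probabilities.
* **One logit + sigmoid.** The binary head outputs a single logit; the
  cross-entropy on the resulting probability is exactly the stated
  two-term loss.
* **Batch norm.** Biased variance for normalisation, unbiased for the
  running estimate, momentum 0.1, eps 1e-5; evaluation always uses
  running statistics, making eval-mode outputs bitwise reproducible.
* **Initialisation.** He-normal for convolutions (no conv biases — every
  convolution is followed by batch norm), BN scale 1 shift 0,
  strategy-independent initialisation order so that models differing only
  in fusion strategy start from identical weights.
* **Tie-breaks.** Best-validation selection keeps the earlier epoch on
  ties; the Youden-optimal threshold keeps the lowest threshold on ties.
* **Checkpoint safety.** Checkpoints embed the encoder configuration and
  its fingerprint; loading verifies the fingerprint so weights cannot be
  attached to a different architecture.

## Scaled-down experiment sizes

The ablation harness (view count, fusion strategy) runs at a reduced
world — 8×16×16 volumes, three views, 500 cases, a small encoder
(channels 2/4/8/16, embedding 16), 25 epochs — so that a mean over five
seeds of seven training runs each completes in minutes on one CPU. The
comparisons are statistical tendencies (means over seeds of runs on
identical data with identical seeds), not reproductions of any printed
AUC gap. The case count matters: with ~100 training cases and a fused
feature of dimension ≥ the case count, the fused head can linearly
memorise the training set, and probability-averaging over per-view heads
(which see n times more samples at 1/n the dimension) dominates; the
feature-over-label ordering only emerges once the fused head has enough
cases to generalise.

## Known limitations

* The DICOM reader supports uncompressed little-endian transfer syntaxes
  only, and the NIfTI reader the common scalar datatypes; both are
  deliberately minimal (no R package for these formats is available in
  the supported environment). Patient-identifying DICOM fields are never
  parsed, so returned objects carry no protected health information.
* Training is single-threaded CPU; the full-scale 512-dim configuration
  is provided and correct but is not sized for desk-scale training runs.
* No data augmentation is implemented: the reference description states
  none, and none was invented.
* With 10-case validation partitions (the 70/10/20 split at 100 cases),
  validation AUC saturates quickly and model selection is coarse; this
  mirrors the small-data regime the method targets rather than a defect
  of the implementation.
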