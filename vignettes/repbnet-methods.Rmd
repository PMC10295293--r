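---
title: "Bilinear RepVGG recognition networks: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilinear RepVGG recognition networks: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`repbnet` identifies individual animals from paired face views. This
vignette explains the model and the pipeline around it, the parameters
that matter, the design decisions taken where reasonable alternatives
existed, and what the synthetic-data experiments do — and do not — show.

## 1. The recognition model

### RepVGG blocks and structural reparameterization

The backbone unit is a RepVGG block. In **training form** it sums three
batch-normalised branches before a shared ReLU: a 3×3 convolution
(padding 1), a 1×1 convolution (padding 0), and — only when `in_ch ==
out_ch` and stride is 1, so the shapes match — an identity branch that is
batch norm alone. Convolutions carry no bias; the BN shift β plays that
role. The multi-branch structure helps optimisation; it is not needed at
inference.

**Reparameterization** converts the block to a single 3×3 convolution
plus bias. For each branch, conv–BN folds as

$$W'_{o} = \frac{\gamma_o}{\sigma_o} W_{o}, \qquad
  b'_o = \beta_o - \frac{\gamma_o \mu_o}{\sigma_o},
  \qquad \sigma_o = \sqrt{\mathrm{var}_o + \varepsilon},$$

the 1×1 kernel is embedded at the centre of a zero 3×3 kernel (with
padding 1 this computes the same map the 1×1 computed with padding 0),
and the identity branch becomes the delta kernel $K[c,c,\cdot,\cdot]$
centred likewise. The three fused kernels and biases sum. The transform
is exact linear algebra; in double precision the train/deploy forward
difference is at rounding level (~1e-13 in our tests), far inside the
1e-4 (block) and 1e-3 (network) tolerances the test suite asserts. Those
tolerances are set for 32-bit-style accumulation error across wide
layers, and "lossless" should be read algebraically, not bit-exactly.

Numerical choices: ε = 1e-5 inside σ (standard BN inference arithmetic;
the fold is written against `sqrt(var + eps)` so a freshly initialised
block with var = 1 is also handled exactly); all convolutions are dense
(group count 1); ReLU follows the three-way sum, not the individual
branches, which is what makes the pre-activation sum fusable.

### Shuffle attention

After every stage an SA module recalibrates features. The C channels are
split into G groups; each group is halved. The first half gets a
*channel* gate `sigmoid(w1 · GAP(x) + b1)` (one value per sub-channel per
sample), the second a *spatial* gate `sigmoid(w2 · GN(x) + b2)` where GN
is group normalization over the sub-channels (one normalization group,
ε = 1e-5, with its own affine scale/shift). Halves are re-concatenated
and a channel shuffle with two groups (the reshape–transpose permutation)
cross-swaps information between the gated halves. Parameters are shared
across the G groups — six vectors of length C/(2G) per module — so the
overhead is negligible (336 parameters across a full bilinear network).

The group count G defaults to 32, the reference default for this
attention family, clamped so C/(2G) ≥ 1 at narrow stages (at C = 8 the
effective G is 4). Gate parameters initialise to scale 0 / shift 1, so
training starts from a mild, uniform gate (σ(1) ≈ 0.73) rather than a
saturated one.

### Bilinear assembly

Two *structurally identical but weight-independent* branches process the
front and side view; sharing weights would halve the parameter count and
presume the two poses share low-level statistics, which face crops from
different angles do not. Each branch has five stages (depths 1, 2, 4, 14,
1), the first block of each stage downsampling with stride 2: 224 px →
7×7 at the 1280-channel head, 32 px (the test scale) → 1×1.

Stage widths are 64, 64, 128, 256, 1280. Among candidate width ladders
this is the configuration that reproduces the published parameter counts
of this architecture exactly — 12,862,504 (12.86 M) for a single branch
at 40 classes, 25,674,104 (25.67 M) for the bilinear+SA training form,
23,069,304 (23.07 M) after reparameterization — so it is fixed as the
default.

Fusion is element-wise **sum** at the final feature map. Sum keeps the
classifier at 1280×40, which is what the parameter counts above require;
it also makes the bilinear model with identical branches and identical
inputs exactly twice the single-branch pre-classifier contribution, a
property the tests exploit. Element-wise product and channel
concatenation are available as `fusion = "product"` / `"concat"` for
ablations. SA modules sit after each stage, inside the branch (stage →
SA → next stage).

## 2. The pipeline around the model

**Deduplication.** Consecutive video frames are near-duplicates. Each
frame is reduced to a normalized luminance histogram (ITU-R BT.601 luma,
256 uniform bins over [0, 256) — the natural reading of an 8-bit
single-axis histogram) and compared to the most recently *retained* frame
with

$$S = \frac{1}{N}\sum_{i=1}^{N}\Bigl(1 - \frac{|g_i - s_i|}{\max(g_i, s_i)}\Bigr),$$

dropping the frame iff S > 0.8 (strictly; S equal to the threshold
keeps). A bin empty in both histograms contributes 1: the values are
equal, and the alternative convention (0) would make any two sparse
histograms maximally dissimilar. The flip side, which users should know:
with 256 bins, two images with *disjoint* narrow histograms still share
many empty bins and can score S ≈ 0.5–0.9. The statistic is a
near-duplicate detector, not a general similarity; for coarse images use
fewer bins (`n_bins`). Comparison is streaming (against the last retained
frame, not all pairs), which is order-deterministic and idempotent:
filtering a filtered sequence is a no-op. Note the threshold direction:
raising the threshold makes elimination harder and so retains *more*
frames; the retained count is monotone non-decreasing in the threshold on
drift-monotone sequences.

**Augmentation.** Five photometric transforms, applied online per batch
(offline expansion would inflate storage and fix the noise realisations):
horizontal flip, brightness (`factor·x`), saturation (blend with the
per-pixel BT.601 gray; factor 0 desaturates), contrast (scaling about the
image mean; factor 0 collapses to the mean), and additive Gaussian noise.
Magnitudes are not prescribed by the architecture, so mild standard
defaults are used: factors ~ U(0.8, 1.2), flip probability 0.5, noise
σ = 10 intensity units, each transform firing independently with
probability 0.5; all configurable and fully seeded. Brightness requires a
positive factor; saturation and contrast additionally accept 0, their
natural collapse limits.

**Pairing and training.** The two-input model consumes same-identity
(front, side) pairs; `make_pairs` also offers `same_view` pairing (two
distinct images of one identity and view) as the mechanism for running
single-view datasets through a two-input model, and a deterministic
`fixed` strategy for evaluation. Training is Adam (β = 0.9/0.999,
ε = 1e-8) under a cosine-annealed learning rate
`lr0·(1 + cos(π·epoch/total))/2`, batch 32, cross-entropy on the
classifier outputs, with an 80/20 stratified validation split; all
randomness flows from one seed and identical seeds give identical
histories. Full-scale defaults are lr0 = 1e-4 and 150 epochs. Inputs are
scaled to [0, 1] and standardised with dataset statistics estimated at
fit time. Batch norms use batch statistics while training and
momentum-0.1 running statistics for evaluation and fusion.

**Metrics.** One-vs-rest confusion counts per class; precision
TP/(TP+FP), recall TP/(TP+FN), F1 their harmonic mean, averaged
**macro** (unweighted over classes — the standard convention when a
single figure is reported for a balanced multi-class problem); accuracy
is overall correct/total. A class with a zero denominator contributes 0
rather than NaN.

## 3. The synthetic data, and what passing tests show

No animal imagery ships with or is downloaded by the package; the study's
data is emulated procedurally. Each identity is a low-dimensional
signature in two parts: a stripe configuration (base gray, frequency,
orientation, phase) rendered in the front view, and a Gaussian-blob
constellation rendered in a mirrored, narrower side-view ellipse.
Crucially, the parts are shared between identities — identity *i* shows
stripe configuration ⌈i/2⌉ and blob configuration ⌈(1 + (i mod n))/2⌉ —
so each single view is ambiguous between roughly two identities while the
*combination* of views is unique for every n ≥ 3. This bakes in the
premise of the two-branch design: fusing complementary views is strictly
more informative than either view alone. (n = 2 degenerates to fully
distinct per-view parameters.) Repeated renders of one identity differ by
seeded jitter: stripe-phase shift, blob displacement, brightness offset,
pixel noise.

Frame sequences for deduplication are a rounded canonical render whose
gray levels shift cyclically by a fixed drift per frame: drift 0 gives
identical frames (S = 1), and the cyclic shift preserves the histogram's
shape while moving its location, so consecutive-frame similarity
decreases cleanly with drift.

The learnability experiments run at a deliberately small scale: 8
identities × 25 images per view at 32 px, a width-(8, 8, 16, 16, 32)
model, lr0 = 1e-3 (appropriate for Adam at this width and sample count,
where the full-scale 1e-4/150-epoch schedule would be needlessly slow),
30 epochs, three seeds. The 25-per-view count makes the stratified 20%
hold-out 40 pairs, so accuracy is measured on a 2.5% grid. Under these
conditions the bilinear model reliably reaches 100% held-out accuracy
while the single-branch ablation, seeing one ambiguous view at a time,
plateaus near the ~50% ceiling its view ambiguity implies — reproducing
the *direction* of the published ablation (two fused views beat one
view).

What this does and does not show: synthetic stripes and blobs are
linearly well-separated textures with no pose deformation, occlusion,
lighting structure, or background clutter. Passing these tests
demonstrates that the architecture, its gradients, its reparameterization
and its training loop are correct and that view fusion works as designed
— it says nothing quantitative about accuracy on real animal faces, and
the published real-data accuracy figures are deliberately not targets of
any test here.

## 4. Degenerate inputs, tie-breaks, and limitations

* `which.max` resolves tied class scores to the lowest index; evaluation
  is otherwise deterministic.
* Empty images, mismatched bin counts, non-divisible channel/group
  combinations, out-of-range class labels, and shape-mismatched fusion
  inputs raise immediate errors rather than propagating NaNs.
* `filter_frames` of an empty sequence is an empty sequence, not an
  error; an identity lacking a required view is skipped by `make_pairs`
  with a warning.
* Reparameterizing an already-deploy object warns and returns it
  unchanged.
* Everything is double precision and CPU-bound; the full 224 px A1-scale
  model builds and reparameterizes in seconds, but *training* at that
  scale in R is not practical — the training loop is intended for the
  reduced scales the tests use. The test suite checks full-scale
  correctness via parameter counts and train/deploy forward equivalence
  (at a reduced spatial grid, which the fusion algebra is independent
  of).
* Batch-norm running statistics use momentum 0.1 with the unbiased
  variance correction; evaluation immediately after very few batches
  reflects that warm-up.
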