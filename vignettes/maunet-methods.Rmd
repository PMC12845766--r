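---
title: "Methods: balance-aware patch augmentation and a lightweight asymmetric U-Net for nucleus segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balance-aware patch augmentation and a lightweight asymmetric U-Net for nucleus segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nucleus segmentation labels every pixel of a microscopy image as nucleus
(foreground) or background. Two features of real benchmark data — such as
the 2018 Data Science Bowl collection (BBBC038) — drive the design of this
package: images arrive in heterogeneous sizes from many instruments and
staining protocols, and background pixels vastly outnumber nucleus pixels.
A segmentation network trained naively on such data is rewarded for
predicting background everywhere; the pipeline implemented here counters
that with a balance-aware patch-extraction stage in front of a deliberately
small U-shaped network.

## Adaptive patch augmentation

Each image of height $h$ and width $w$ is covered by $k \times k$ windows
moved with stride $s$ and zero padding:

$$p_h = \left\lceil \frac{h-k}{s} \right\rceil + 1, \qquad
  p_l = \left\lceil \frac{w-k}{s} \right\rceil + 1, \qquad
  N = p_h \, p_l .$$

The ceiling lets the final stride overshoot the image border. Because the
padding is fixed at zero, the implementation clamps the final window origin
per axis to $h-k$ (resp. $w-k$), creating extra overlap at the border
rather than padded pixels. Clamped origins are *not* deduplicated even when
they coincide with the previous origin, so the count identity $N = p_h p_l$
holds exactly — the grid equations, not the geometry, define how many
patches an image yields.

A patch is kept only when its foreground pixel count *strictly exceeds* a
threshold (default 9 pixels). The number of discarded patches per image is
the improper-class-distribution count $\alpha$, leaving

$$N_\alpha = p_h \, p_l - \alpha$$

patches. Discarding (near-)empty patches raises the foreground fraction of
the training ensemble; the per-image balance report (columns `N`, `alpha`,
`N_alpha`, `fg_fraction_before`, `fg_fraction_after`) makes the effect
measurable. $\alpha$ is accounted per image and summed for dataset-level
reporting. A dilation parameter exists in the interface for completeness
but is fixed at 1; it never enters the grid equations.

Parameter choices that matter:

* `k = 128` — the network's native input size.
* `s = 64` — the stride is a free parameter of the scheme (no canonical
  value exists); 64 gives 50% overlap at `k = 128`, which is deliberate:
  overlapping windows let neighbouring patches share features and increase
  the effective sample count.
* `alpha_threshold = 9` — a patch must contain at least 10 foreground
  pixels to survive. (A remark sometimes attached to this threshold, that
  it guarantees ~10% foreground coverage, is arithmetically wrong —
  9 of $128^2$ pixels is about 0.05% — and is ignored; the pixel count is
  what is implemented.)
* `aug_fraction = 0.25` — a random quarter of the kept *training* patches
  additionally receive a randomly composed transform from {vertical flip,
  horizontal flip, rotation by a random multiple of 90°, Gaussian blur}.
  The transformed copies are appended to the ensemble (offline
  augmentation); geometric transforms are applied identically to image and
  mask, blur to the image only, so masks stay binary and their foreground
  counts are invariant.

Images smaller than `k` in either axis are mirror-padded up to `k` (with a
message) before extraction, since the scheme must accommodate arbitrary
input sizes.

## The network

The model is a six-level encoder–decoder with skip connections operating on
$128 \times 128 \times 3$ inputs. Every block consists of two $3\times3$
same-padded convolutions, each followed by ReLU, with one dropout layer per
block. A $2\times2$ max-pool heads downblocks 2–6 and the middle block; a
$2\times2$ stride-2 transposed convolution heads each upblock, and its
output is concatenated with the final feature map of the matching encoder
block. The head is a $1\times1$ convolution to 2 channels with a per-pixel
softmax.

The channel schedule is what makes the model lightweight and asymmetric:

| stage | conv1 | conv2 |
|---|---|---|
| downblocks 1–4 | 8, 16, 32, 64 | same as conv1 |
| downblock 5 | 128 | **16** |
| downblock 6 | 256 | **32** |
| middle | 512 | 64 |
| upblocks 6–1 (conv1) | 256, 128, 64, 32, 16, 8 | |
| upblocks 6–1 (conv2) | | 32, **16**, 64, 32, 16, 8 |

The second convolutions of downblocks 5 and 6 collapse to a quarter and a
half of downblock 4's width, which shrinks both the skip tensors and the
transposed-convolution fan-in; the upblock conv2 schedule mirrors this
asymmetry. The layer table is followed literally even where it breaks
decoder symmetry (upblocks 6 and 5). `shape_trace()` reproduces the table
analytically and is what the tests and the acceptance script read.

Interpretation choices where the block structure is genuinely open:

* **Pooling placement.** The pool sits at the *head* of downblocks 2–6 and
  of the middle block — the only placement consistent with the traced
  spatial sizes (the first downblock works at full resolution).
* **Middle block order.** pool → conv(512) → conv(64) → dropout, with the
  upsampling transposed convolution implemented as the head of upblock 6;
  this is the only order consistent with a 2×2×512 then 2×2×64 bottleneck.
* **Decoder order.** transposed conv → concatenate skip → conv → ReLU →
  conv → ReLU → dropout, the standard U-Net decoder.
* **Skip source.** The second convolution's output of each downblock (the
  block's final feature map, e.g. 8×8×16 for downblock 5).
* **Transposed-conv width.** Set to the destination upblock's conv1 filter
  count (not otherwise specified).
* **Dropout.** Rate 0.2, once per block after the second activation.
* **Initialization.** Seeded He-uniform for all convolution weights
  (suited to ReLU), zero biases. No pre-trained weights anywhere.

`maunet_spec(width_scale = w)` scales every filter count by `w` (rounded,
floor 1, output head fixed at 2 classes) for width-reduced variants used in
small experiments; `width_scale = 1` is the canonical table.

### The numerical engine

No deep-learning framework is used: the forward pass and backpropagation
are implemented in the package. Stride-1 same convolutions are evaluated as
im2col + GEMM through BLAS (RcppArmadillo); the 2×2 pooling and stride-2
transposed convolution use direct loops. The backward pass is verified
against central finite differences in the test suite. One subtlety the
tests document: at the He/zero-bias initialization, whole regions of
pre-activations sit *exactly* at the ReLU kink (zero bias plus ReLU-zeroed
input windows), where a finite-difference probe straddles the subgradient —
gradient checks are therefore performed at a jittered parameter point.

## Training protocol

Adam with decoupled weight decay (the weight-decay term multiplies the
parameter directly rather than entering the moment estimates), binary
cross-entropy loss, and a stepwise learning-rate schedule:

$$\mathrm{lr}(e) = \mathrm{lr}_0 \cdot
  \gamma^{\lfloor e / (f \cdot E) \rfloor}$$

with 0-based epoch $e$, decay $\gamma = 0.5$, interval fraction $f = 1/8$
of the total epoch budget $E$. Defaults follow the published protocol:
$\mathrm{lr}_0 = 3\times10^{-4}$, batch 64, $E = 500$, weight decay
$10^{-4}$, dropout 20%, early-stopping patience 50, seed 42. With the
default budget the rate is constant for 62.5-epoch stretches and takes at
most 8 distinct values; note that for short runs the interval shrinks
proportionally, so small-epoch smoke tests set `interval_fraction = 1`.

The network's two softmax channels are trained with the cross-entropy of
the foreground channel, which for two classes is identical to categorical
cross-entropy; probabilities are clipped at $10^{-7}$ before logarithms.
After every epoch the validation set is scored (precision, recall, F1,
MeanIoU from pooled confusion counts); the checkpoint with the best
validation F1 (MeanIoU as tie-breaker) is kept, and training stops early
after `patience` epochs without improvement of that same quantity. All
randomness — weight initialization, shuffling, dropout — derives from the
config seed, so identical calls reproduce identical fits. A non-finite
loss aborts with the epoch named.

## Evaluation

From pixel confusion counts (foreground = nucleus = positive class):
precision $tp/(tp+fp)$, recall $tp/(tp+fn)$, F1 as their harmonic mean,
per-class intersection-over-union $tp/(tp+fp+fn)$ and $tn/(tn+fp+fn)$, and
MeanIoU as the arithmetic mean of the two class IoUs — the usual
convention of segmentation toolkits when a "mean" IoU is reported for a
binary task. Counts are pooled over all evaluated patches before the
ratios are taken (micro-averaging); per-patch macro-averaging is available
behind a flag. Vacuous $0/0$ ratios (an all-background patch predicted
all-background) are defined as 1. Probability maps are binarized by
channel argmax with exact ties assigned to foreground.

Evaluation is performed on the ADA patches of the test images, the same
representation the model trains on; `segment_image()` additionally offers
whole-image prediction by averaging overlapping patch probabilities, but
that is not the reported default. Published benchmark figures on the
external Data Science Bowl dataset (MeanIoU ≈ 0.955 for this architecture)
require the external data, full 500-epoch training and an unstated
extraction stride, and are therefore out of scope here; the package's
property and acceptance tests substitute verifiable synthetic-data checks.
One further documented inconsistency: the published comparison table
reports an F1 exceeding both its precision and recall, which is impossible
for a harmonic mean; this package computes F1 strictly from its
definition.

## Synthetic data

The generator renders randomly oriented, possibly overlapping ellipses
(radii 4–10 px by default) over a low-frequency Gaussian-textured
background, adds per-pixel Gaussian noise (σ = 8 intensity units) and
slight per-channel gain jitter, and returns the exact rendered union as
ground truth. Nuclei are placed around 1–3 random cluster centres, as
cells grow in colonies; this produces the near-empty regions that make the
class-imbalance problem visible at patch level. Image sizes are drawn from
192–320 px to emulate heterogeneous acquisition; the default foreground
fraction (~5%) is a documented package choice for "strong background
dominance" — no canonical value exists. Instance masks are written one
file per nucleus in the `<id>/images/`, `<id>/masks/` folder layout so the
reader's union-merge path is exercised end to end.

What the generator does *not* emulate: realistic stain variation,
out-of-focus artifacts, touching-nuclei boundary ambiguity, annotation
noise. Passing tests on synthetic data therefore demonstrate that the
pipeline's machinery (extraction arithmetic, balance filtering, learning
dynamics, metric computation) is correct, not that the model reaches any
particular accuracy on real microscopy.

## Data handling choices

* The 80:10:10 split is computed on whole images, before patch extraction,
  with the deterministic rule train = ⌊0.8 n⌋, validation = ⌊0.1 n⌋,
  test = remainder; sizes always sum to n. (Published per-subset counts
  for the external benchmark are internally inconsistent with an exact
  80:10:10 split, so no printed count is treated as normative.)
* Instance masks are binarized at intensity > 0 and unioned; the task is
  binary semantic segmentation, not instance segmentation.
* Grayscale images are replicated to three channels; RGBA drops alpha.
* Images keep their native size until patch extraction.

## Problem sizes used by the tests

The test-suite sizes are package choices made to keep the default runs
small: unit tests use 64–320 px synthetic images and width-reduced
networks (`width_scale` 0.05–0.25); the end-to-end learning check trains a
`width_scale = 0.25` model on a 64-image synthetic dataset (~5%
foreground, seed 42, ADA `k = 128`, `s = 64`, threshold 9) for 30 epochs
at batch size 8 — small enough for a single CPU, large enough for the
model to segment held-out synthetic patches well.

Short-budget optimizer settings deserve a note. The protocol's learning
rate of $3\times10^{-4}$ is paired with a 500-epoch budget whose schedule
holds it constant for the first 62.5 epochs. Training a class-imbalanced
segmentation task passes through a long background-collapse phase (the
network first matches the background prior, and only later becomes
confident on foreground pixels); at $3\times10^{-4}$ that escape takes
more epochs than a 30-epoch budget contains, so the short runs use a
constant $10^{-3}$ — the same order, scaled for the compressed budget —
with dropout, weight decay, batch-shuffling and checkpoint selection
exactly as in the full protocol. The full-protocol defaults remain the
package defaults.

## Known limitations

* Single CPU, double precision, no GPU path; full-width 500-epoch training
  at benchmark scale is out of reach of the bundled engine.
* MeanIoU follows the two-class convention; comparisons against tools that
  average only the foreground IoU will differ.
* The balance filter operates on ground-truth masks and is therefore a
  training-time device only; at inference the full grid is used.
* Patch-level evaluation counts overlapping pixels more than once when
  `s < k`; stitched whole-image evaluation avoids that but is optional.
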