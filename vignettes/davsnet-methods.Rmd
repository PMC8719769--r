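---
title: "DAVS-Net in R: model, training objective, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DAVS-Net in R: model, training objective, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(davsnet)
```

This vignette is the package's own account of the science it implements: the
segmentation network and its assumptions, the training objective, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions taken where the published description left the matter open.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## The model

DAVS-Net is a fully convolutional encoder–decoder for two-class semantic
segmentation of retinal vessels. The encoder has three dense blocks; each
applies a 3×3 convolution (Conv-A), batch normalization and ReLU, a second
3×3 convolution (Conv-B), and concatenates the two convolution outputs
depth-wise. A 1×1 bottleneck convolution then halves the concatenated depth,
and a 2×2/stride-2 max-pool halves the spatial size while recording the
argmax position of every window. The channel plan is 64/64 → cat 128 →
bottleneck 64, then 128/128 → cat 256 → bottleneck 128, then 256/256 →
cat 512 → bottleneck 256, so a 640×640 input reaches the decoder as an
80×80×256 map — the network's deepest point, deliberately kept at 1/8 scale
to limit spatial information loss.

The decoder mirrors this: each block starts with max-unpooling driven by the
indices transferred from the mirrored encoder pool (placing values at their
original positions rather than interpolating), applies Conv-A/BN/ReLU and
Conv-B, and concatenates *three* maps: the two decoder convolutions plus the
mirrored encoder block's Conv-A activation, delivered by an outer dense path.
These skip paths carry edge information directly from early encoder layers to
late decoder layers. The decoder bottlenecks map 640 → 128, 320 → 64 and
130 → 2 channels; the final two-channel map (vessel, background) passes
through a per-pixel softmax, and classification takes vessel iff
P(vessel) > P(background), ties to background.

One declarative graph (`build_davsnet_graph()`) drives both the symbolic
audit (`propagate_shapes()`, `count_parameters()`, `audit_architecture()`)
and the executable model (`init_davsnet()`, `davsnet_forward()`), so runtime
shapes and allocated parameters are checked against a single source of truth
rather than two parallel descriptions.

## Reconciling the published layer table

The published per-layer table is reproduced cell-for-cell by the audit, with
two rows that are arithmetically inconsistent *as printed* and are therefore
flagged `RECONCILED` rather than silently corrected:

* **E-Bneck-2** is printed as an exact copy of the E-Bneck-1 row
  ("1×1×128, 64 filters, 8256 + 128, output 640×640×64"). Two independent
  printed cells contradict it: Pool-2's output is printed 160×160×**128**,
  and EDB3-C1's printed 295,168 parameters equal 3·3·**128**·256 + 256. Both
  force a 256 → 128 bottleneck: 32,896 weights+biases, 256 BN terms, output
  320×320×128.
* **DDB3-C2** prints 64 filters against its own printed 295,040 parameters
  (= 3·3·256·**128** + 128) and the printed 640-deep block-3 concatenation
  (256 + 128 + 256). Reconciled to 128 filters.

A handful of further cells are obvious transcription slips that touch no
parameter arithmetic (decoder block-2 rows carry encoder labels; a few output
cells echo a neighbouring row); the audit keeps their printed values, notes
the inconsistency, and matches on the parameter cells.

### Batch-norm placement

The published notation marks certain layers as "includes ReLU and BN after",
and its prose can be read as placing BN/ReLU on the concatenation output,
before the bottleneck. The printed BN parameter cells decide the question:
every "+2·C" term equals twice the *output* channels of the marked layer
(+128 on a 64-channel bottleneck, +256 on a 128-channel one, +4 on the final
2-channel one), whereas BN on a concatenation output would cost twice the
concatenated depth and match no printed cell. This package therefore attaches
conv → BN → ReLU to every marked layer (the six Conv-A's and six
bottlenecks), and gives Conv-B outputs no separate BN/ReLU before the
concatenation — again as the absent "+" terms on those printed rows indicate.
Whether the authors intended conv→BN→ReLU or conv→ReLU→BN ordering cannot be
settled from the text; conv→BN→ReLU (the common order) is used and stated
here rather than guessed as authorial intent.

BN accounting counts only the learnable scale and shift (2·C); running
statistics are not trainable and are not counted. Biases of convolutions
that feed straight into BN are mathematically redundant (the mean
subtraction absorbs them) but are allocated and counted because the printed
table includes them.

## Training objective and protocol

Vessel pixels are heavily outnumbered, so the loss is a weighted
cross-entropy with **median frequency balancing**: for each class,
freq_c = (pixels of class c) / (total pixels of images where c occurs), and
weight_c = median(freq)/freq_c — with two classes the median is the midpoint
of the two frequencies. The loss is the mean over evaluated pixels of
−w_c(p) · log P_c(p)(p), with probabilities floored at 1e−12 so a confidently
wrong pixel yields a large finite loss rather than −∞ (the floor is far below
any probability a finite-logit softmax produces, so gradients are unaffected
in practice).

The optimizer is Adam with initial learning rate 1e−3 and mini-batches of 10
images, following the published recipe. The published "exponential decay rate
of 0.9" is read as the *first-moment* decay — the hyperparameter that phrase
conventionally describes — with the second-moment decay at Adam's customary
0.999; this reading is a decision, not a quotation. The learning rate is
constant (no schedule is claimed), and the training length is an explicit
configuration value: no epoch count is published.

Two further openings are resolved as follows. Whether out-of-FOV pixels
contribute to the loss is unstated; both behaviours are supported
(`training_config(use_fov = )`), defaulting to including all pixels, the
simpler reading. Batch statistics for BN are computed per image — images pass
through the network one at a time and mini-batch gradients are averaged
before each update — which is exactly batch-size-1 BN; inference uses running
statistics accumulated with momentum 0.9. Gradients are hand-written
(im2col/col2im convolutions over BLAS, full BN backward, index-routed
pool/unpool backward) and are verified against central finite differences at
1e−4 relative tolerance in the test suite.

For datasets without a fixed train/test split, `leave_one_out_splits()`
produces the n-fold hold-one-out plan: n folds, each training on n−1 samples,
every sample held out exactly once, in deterministic order.

## Augmentation

The published augmentation names two transforms: rotating each training image
in 1-degree steps and randomly increasing/decreasing brightness. Rotation is
about the image centre with canvas preserved and exposed corners filled with
background; images interpolate bilinearly while vessel and FOV masks rotate
nearest-neighbour so they remain strictly binary. Brightness is a
multiplicative factor clipped to [0, 1], masks untouched. The brightness
interval is unpublished; the default [0.8, 1.2], sampled uniformly, is
conservative, configurable, and by construction contains factors on both
sides of 1.

The published variant totals (7,600; 7,000) are not unambiguously derivable
from the stated transforms. The package does not assert them by default;
`augmentation_preset_full_rotation()` encodes the one consistent reading —
360 rotations plus 20 brightness variants per image — which reproduces 7,600
for a 20-image training set, and the acceptance suite asserts exactly that
count. `build_augmented_set()` returns a deterministic manifest plus a lazy
`realize_variant()` materializer: 7,600 full-resolution variants have no
business existing in memory at once.

## The synthetic generator: what a green test establishes

`generate_fundus_sample()` emulates the inputs the real datasets provide — a
bright circular field of view on a dark background, a recursive binary
branching vessel tree entering at the disc edge (1–2 root stems; children get
angle offsets drawn within ±spread and caliber multiplied by 0.75 per
generation, terminating below one pixel or at the FOV boundary; smooth
centerline curvature), vessels rendered darker than the green-dominant
textured background, radial illumination falloff, additive Gaussian noise —
with pixel-perfect vessel and FOV masks and bit-exact reproducibility from
the seed. The caliber decay reproduces the major-vessel/minor-vessel scale
mixture that motivates dense aggregation in the first place.

Defaults are chosen once for realism at realistic sizes: vessel fraction
bounded to 3–15% of the FOV (real vasculature sparsity), initial caliber
about 1.8% of the image side (≈12 px at 640, ≈2 px at 64), branch depth 6,
contrast 0.35, illumination amplitude 0.25, noise SD 0.03. At toy sizes
(≤32 px) the 3–15% window is geometrically infeasible — any visible tree
covers more of the tiny disc — so toy test fixtures pass explicitly relaxed
parameters; the defaults are not adjusted to accommodate them.

What the generator does *not* emulate: pathology (lesions, exudates,
neovascularization), the optic disc and macula, vessel crossings with
realistic junction geometry, camera vignetting and compression artifacts, and
inter-observer ambiguity in the ground truth. A model that segments these
images well has demonstrated that the architecture, loss, gradients and
training loop work — the overfit smoke test and the beats-the-empty-baseline
property are engineering checks, not clinical claims. The published benchmark
accuracies on DRIVE/STARE/CHASE_DB1 require the real images and GPU-scale
training and are out of scope here.

## Numerical choices

* **Pooling ties** keep the first maximum in row-major window order, making
  index transfer deterministic; **classification ties** (P = 0.5) go to
  background.
* **ROC-AUC** integrates by trapezoids over all distinct thresholds,
  equivalent to the Mann–Whitney statistic with ties counted 0.5 (the
  published text does not specify tie handling).
* **AUCPR** uses the step-wise average precision Σ(R_k − R_{k−1})·P_k rather
  than trapezoids: only the step form yields the random-classifier baseline
  equal to prevalence (constant scores → AUCPR = vessel fraction), the
  property the evaluation leans on under heavy class imbalance. Precision at
  zero predicted positives is defined as 1.
* **Zero denominators** in Se/Sp/Acc produce NA with a warning, never a
  silent 0; single-class truth makes ROC undefined and is rejected.
* Metrics are computed per image *and* pooled by summing confusion counts
  (the publication does not state which aggregation its tables use); both
  rows appear in `evaluate_segmentation()` output.
* All metrics are FOV-restricted when a FOV mask is supplied, including the
  curve areas (the published accuracy text says "FOV only"; the AUC text is
  silent — the stricter reading is applied uniformly).
* **Initialization** is fan-in-scaled normal (sd = sqrt(2/fan_in)) with a
  seed: the network is trained from scratch and the publication specifies no
  scheme, so the choice optimizes reproducibility, not fidelity.
* **Geometry policy**: native-size inputs are resized to the configured
  network size (bilinear for images, nearest for masks) and predictions are
  mapped back nearest-neighbour before evaluation; the publication never
  states its handling of the three datasets' differing native sizes.

## Interfaces and formats

Rasters are NetPBM (binary/ASCII PGM and PPM, 8- or 16-bit): masks
round-trip exactly at 8 bits, images at 16-bit quantization precision. No
PNG/TIFF codec is available to the package, so those formats are not read;
NetPBM is the portable plain-raster fallback. Dataset manifests are CSV
(id, image, truth, fov, split) with FOV optional — when absent, a stand-in
FOV is synthesized as the largest bright connected region of the image.
Checkpoints are self-describing RDS containers (graph plus named parameter
arrays); save → load → forward is bit-exact. Tabular results — audits,
metrics, manifests, split plans, loss histories — are tibbles, with
`tidy()`/`glance()` on fits and `autoplot()` on curves, fits and synthetic
samples; activation volumes remain plain numeric arrays, which is what they
are.

## Known limitations

Pure-R execution is desk-scale: a 64×64 forward-plus-backward pass costs
roughly a second on one CPU, and 640×640 training is out of reach (a single
640×640 forward pass allocates multi-gigabyte im2col buffers). Two-class
only; no test-time augmentation; no learning-rate schedules or early-stopping
policy beyond the optional training-accuracy stop; per-image BN statistics
differ from what multi-image-batch BN would compute; the FOV synthesizer is a
threshold-plus-largest-component heuristic, adequate for bright-disc images
only.
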