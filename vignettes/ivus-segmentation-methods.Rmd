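---
title: "Methods: automatic lumen and EEM segmentation of coronary IVUS frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic lumen and EEM segmentation of coronary IVUS frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Intravascular ultrasound (IVUS) produces short-axis cross-sections of a
coronary artery during catheter pullback. Two contours carry most of the
clinical information: the **lumen** border (the blood channel) and the
**external elastic membrane (EEM)**, the media--adventitia interface. Their
areas give plaque burden and drive stenting decisions, but manual
delineation of hundreds of frames per pullback is slow and
reader-dependent. `ivusseg` implements a fully automatic pipeline: a deep
encoder--decoder convolutional network classifies every pixel of a 512x512
frame into background, lumen, or the EEM ring, trained with online
flip/rotation augmentation and optional per-pixel coordinate ("MeshGrid")
channels.

## Class encoding

A softmax classifier needs mutually exclusive classes, but the EEM-bounded
cross-sectional area (EEM-CSA) geometrically *contains* the lumen. The
package therefore stores exclusive labels

* 0 — background (adventitia and everything outside the EEM),
* 1 — lumen,
* 2 — EEM ring (EEM-CSA minus lumen),

and reconstructs the clinical EEM-CSA region as labels `{1, 2}` at
evaluation time. Both readings of the EEM metric are reported:
`eem_csa_mode = "ring"` scores the exclusive ring class and
`"filled"` scores the merged region as a binary task. On nested masks the
filled reading can only be more favourable (the contested inner border
disappears), which the test suite checks empirically.

## Network

`model_config()` / `build_unet()` construct a U-Net with `depth` stride-2
downsamplings; the clinical geometry uses `depth = 8` at 512x512, giving 9
encoder blocks, 8 decoder blocks and a 2x2 bottleneck. Each encoder block is
two units of [3x3 convolution -> batch normalization -> LeakyReLU];
downsampling between blocks is a *separate* 3x3 convolution with stride 2
(also batch-normalized and activated, completing the block symmetry). Each decoder block is a
5x5 stride-2 transposed convolution that exactly doubles the spatial size,
concatenation with the same-resolution encoder output, then the same two
conv--BN--LeakyReLU units as an encoder block. A 1x1 convolution and
softmax produce per-pixel class probabilities.

Design choices the architecture description leaves open, fixed here:

* **Channel schedule**: `base_channels` (default 32) doubling per
  downsampling, capped at `max_channels` (default 512) — the conventional
  U-Net schedule.
* **LeakyReLU slope** 0.01, configurable.
* **Initialization**: He-style random normal for all convolutions, no
  pretrained-weight transfer. This encoder's channel schedule matches no
  published VGG-style weights, and random initialization keeps runs fully
  reproducible from one seed; where transfer learning would plug in is
  noted in `build_unet()`.
* **Batch norm**: biased batch moments during training, running averages
  (momentum 0.1) frozen for inference.
* Ties in the argmax decoding break toward the lowest class index, so a
  pathological uniform probability map decodes to all-background.

The network, its backward pass and the Adam optimizer are implemented in
the package itself (BLAS-backed im2col/GEMM kernels in C++, single
precision for the feature-map algebra; statistics and parameters in double
precision). Gradients of every layer were validated against central finite
differences during development, and the suite retains oracle checks of the
loss and the fused batch-norm kernel against plain-R references.

## Training protocol

`train_config()` defaults reproduce the full clinical regime: sparse
softmax cross-entropy as the mean over all pixels, background included (a
single three-class softmax trains all structures jointly; no pixel
masking), Adam with framework moment defaults, batch size 16, initial
learning rate 0.001 decayed by 0.1 every 2000 iterations, 8000 total
iterations. Batches are drawn with replacement — an iteration budget, not
an epoch budget — and augmentation is applied online, a fresh draw per
sample per step.

Random draws: rotation is uniform over {none, 90, 180, 270} degrees and
flip uniform over {none, up--down, left--right}, independently. The
identity option is included in each draw, so the undisturbed sample stays
part of the training distribution.

## MeshGrid semantics

"Adding the MeshGrid at pixel level" is read as **concatenating** two
coordinate channels (row/height-1, column/width-1, both in [0,1]) to the
intensity image — the stated purpose is positional information, which
arithmetic addition onto intensities would corrupt. An `"add"` mode is
nevertheless exposed in `augment_config()` for comparison. Coordinate
channels are appended *before* the geometric transforms and are transformed
together with the image, so the network sees original-frame coordinates
under augmentation; `meshgrid_invariant = TRUE` switches to regenerating
them afterwards. At inference the channels are appended un-transformed,
which matches the identity draw of the training distribution.

## Evaluation

`confusion_matrix()` pools per-pixel counts (entry (i,j) = pixels of true
class i predicted j); `iou_per_class()` computes
p_ii / (row_i + col_i − p_ii), with classes absent from both truth and
prediction flagged undefined and excluded from means; `miou()` averages the
defined per-class IoUs over all classes including background. Frames are
pooled pixel-wise before the ratio (micro-averaging, stated in the report
metadata); per-frame macro-averaging is available as an option. Per-structure
IoUs (lumen; EEM-CSA in either reading) are reported alongside the strict
multi-class mean: clinical summaries usually quote one number per
structure, which is not the same quantity as the multi-class mean, so both
are emitted rather than guessing a single reading.

## Synthetic phantoms

No public clinical IVUS corpus with paired lumen/EEM annotations is
available, so the package ships a generator (`phantom_config()`, `make_phantom()`, `make_corpus()`)
whose output has the statistical structure the method relies on:

* nested ellipses (axis ratio 0.7--1.0, random rotation) for lumen and EEM,
  with eccentric lumen placement bounded so containment always holds;
* a dark blood pool (template intensity 0.18), bright media/plaque ring
  (0.72), mid-gray adventitia (0.45), and a bright catheter ring artifact
  around the transducer at the image centre (labelled lumen, as in clinical
  annotations);
* multiplicative gamma speckle of unit mean (`speckle_scale` = dispersion,
  default 0.3) applied to intensities only, never to labels;
* an optional deterministic intensity bias (`gradient_strength`, default
  0.2) combining a vertical and a radial component, emulating
  depth-dependent gain — this is what makes coordinate channels carry
  exploitable signal in the ablation;
* per-patient geometry sampled once and jittered per frame, so frames of
  one patient are correlated as in a pullback, and the train/test split is
  by whole patients (for example 24 train / 6 test in a 30-patient study).

Pixels belong to a region when their centre lies inside the analytic
contour (half-open, centre-sampling rasterization). What the phantoms do
**not** emulate: real speckle statistics and texture, calcified shadows,
bifurcations, stents, motion artifacts. Tests passing on phantoms therefore
validate the pipeline's mechanics and the qualitative value of the
augmentation, not clinical-grade accuracy; IoU values reported on clinical
material are out of reach of any synthetic stand-in and are not asserted
anywhere in the suite.

## Problem sizes used by the tests and the acceptance script

The full 512x512/depth-8 configuration is exercised for its shape and
architecture contracts (block counts, bottleneck size, probability
simplex). Learning behaviour is demonstrated at reduced scale, chosen as
the smallest sizes at which the phantom task is still non-trivial:

* end-to-end learning: 128x128 frames, depth 4, `base_channels` 8, batch 8,
  300 iterations, 64 training frames (8 patients), 16 held-out frames
  (2 patients), three seeds. Narrower models (4 feature maps at full
  resolution) can fail to ever discover the lumen class at this iteration
  budget — an optimization plateau, not a data problem — which is why 8 is
  the smallest width used;
* augmentation ablation (`gradient_strength` 0.3): 64x64 frames, depth 3,
  `base_channels` 8, 200 iterations, 48 training frames (6 patients) with
  16 held-out frames (2 patients), two arms (`none` vs
  `meshgrid_flip_rotate`) by three seeds, compared on mean held-out lumen
  IoU.

`scripts/acceptance.R` re-runs the 128x128 pipeline end to end (corpus
generation, two-arm training, evaluation) from a single seed and writes the
quantities it computes as JSON.

## Numerical choices and edge rules

* Softmax probabilities are clamped to [1e-12, 1-1e-12] before the log.
* Per-frame min--max intensity normalization to [0,1] at DICOM ingest
  (robust to vendor gain); a constant frame maps to all zeros.
* A 1x1 coordinate grid uses the convention 0/0 = 0.
* Learning rate at 0-based step t is lr * factor^floor(t / every):
  piecewise constant, non-increasing.
* Confusion matrices are integer-exact; IoU of an absent class is NA, never
  0 or 1.
* All randomness flows through explicit seeds; corpus generation restores
  the caller's RNG state, and `run_ablation()` derives weight/batch
  substreams from each arm seed so arms differ only in strategy.

## Known limitations

* No early stopping or validation-based checkpoint selection; the
  final-iteration weights are the deliverable.
* Class-imbalance weighting exists (`class_weights`) but is off by
  default: the plain pixel mean is the baseline the ablation compares
  against.
* The DICOM reader covers uncompressed little-endian single/multi-frame
  grayscale files — the subset this pipeline reads and writes — not the
  full standard.
* Single-device, CPU-friendly implementation; no multi-GPU data
  parallelism, mixed precision, or 3-D reconstruction.
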