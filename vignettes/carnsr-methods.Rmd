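---
title: "Methods: channel-attention super-resolution for histopathology patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel-attention super-resolution for histopathology patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carnsr)
```

## The problem

Whole-slide scanners digitize stained tissue sections at multiple
magnifications; scanning at the highest magnification is slow and
expensive. Single-image super-resolution (SISR) reconstructs a
high-resolution (HR) patch from a low-resolution (LR) one, and is a
practical substitute for re-scanning when downstream work — visual reading
or automated classification — needs more detail than the stored level
provides. Histopathology patches differ from natural photographs in two
ways that matter for SISR: the palisade/honeycomb arrangement of cell
tissue puts far more energy into high spatial frequencies, and staining
compresses the color distribution into a narrow pink–purple band. The
model implemented here is built around both observations.

## The network

`carn_model()` builds a residual network of `n_carb` channel-attention
retention blocks (CARBs) operating at LR resolution, followed by sub-pixel
upsampling:

1. **Normalization.** The per-channel dataset means are subtracted from
   the input (and added back to the output), so the network predicts
   residuals around the dataset mean. The default means
   `(0.7204, 0.4298, 0.6397)` are the stained-tissue training-set values;
   `compute_norm_stats()` recomputes them for any dataset.
2. **Head.** One 3×3 convolution lifts RGB to `channels` features
   (`F0`).
3. **Body.** `n_carb` CARBs are chained; a body-tail convolution and a
   long skip add `F0` back (`FN = F0 + Fn`), feeding low-frequency
   content forward so the blocks can spend their capacity on
   high-frequency residuals.
4. **Upsampler.** For scales 2/4/8, one/two/three groups of
   (3×3 convolution `C → 4C`, pixel shuffle ×2); for scale 3, one group of
   (`C → 9C`, shuffle ×3). A final convolution maps back to RGB.

Each CARB computes `out = in + gate ⊙ trunk(in)`, where the trunk is
`convs_per_block` 3×3 convolutions (ReLU between them) and the gate is the
**CA retention** module: global average pooling to a C-vector, a
down-projection, ReLU, an up-projection back to C, and a logistic sigmoid,
applied per channel. Where conventional squeeze-and-excitation gates use a
narrow bottleneck (C/16), the bottleneck here is wide:
`max(1, round(C / reduction))` with `reduction = round(sqrt(C))` by
default, i.e. width 8 at C = 64 — a √C-wide descriptor that loses less
channel information, which matters when high-frequency structure is spread
over many channels, as it is in tissue images.

### Choices the architecture description leaves open

* **Trunk depth.** "Multiple convolutions" per block is read minimally as
  two 3×3 convolutions with a ReLU between them, exposed as
  `convs_per_block`. With this reading the default model has ~0.79 M
  parameters; the published reference budget for the same architecture
  family is 1.389 M, so `carn_complexity_report()` prints its own total
  *beside* the reference instead of asserting equality, and the package
  only asserts what is structurally certain: both parameter and FLOP
  totals are exactly affine in `n_carb`.
* **Gate projections** are 1×1 convolutions on the 1×1 pooled descriptor —
  i.e. dense maps; any larger spatial extent would be meaningless.
* **Gate application.** The retained attention rescales the trunk output
  channel-wise *before* the block's residual addition.
* **Padding** is zero same-padding everywhere, so feature maps keep H×W.
* **Initialization** is Kaiming fan-in for all convolutions with zero
  biases, fully seed-controlled; two models built with the same seed are
  bitwise identical.
* **FLOP convention** (nowhere standardized): 1 MAC = 1 FLOP,
  convolutions only (including the two gate projections), reported at a
  declared LR input size, 128×128 by default.

## The objective

Training minimizes
`L = α·L1 + β·MSE + γ·(1 − SSIM)` with defaults
`(α, β, γ) = (0.8, 0.1, 0.1)`. L1 dominates for robustness to large
errors and sharper texture; the MSE term stabilizes pixel-level accuracy;
the SSIM term rewards local structural agreement, which tracks how
pathologists actually compare images. The loss is computed in image space
(after the means are added back) so the SSIM dynamic range of 1.0 is
well-defined.

SSIM uses the reference parameterization: 11×11 Gaussian window,
σ = 1.5, k1 = 0.01, k2 = 0.03. Local statistics are computed by
same-padded filtering and the (window−1)/2 border of the index map is
cropped before averaging, so every retained window lies fully inside the
image; identical inputs score exactly 1 and constant-shifted constant
images reduce to the closed-form luminance term. Because the Gaussian
window is separable, filtering is implemented as two banded-matrix
products; the symmetry of those bands makes the operator self-adjoint,
which is exactly what the analytic gradient of mean SSIM requires. The
gradient is derived with respect to the five filtered statistics
(means, raw second moments, cross moment) and verified against finite
differences in the test suite, as is the full network backpropagation.

Evaluation reports PSNR (dB, peak 1.0; identical images report `Inf`) and
SSIM on RGB in [0, 1] with no border cropping by default; a
`crop_border` argument exists because published evaluation protocols vary
on this point.

## Data pipeline

* **Degradation.** LR images are produced by bicubic downscaling with the
  a = −0.5 kernel and an antialias prefilter (kernel support widened by
  the inverse scale) — the de-facto standard dialect in SISR work. The
  dialect is pinned and tested because cross-method PSNR comparisons are
  sensitive to it. Degradation happens once per image; training crops are
  taken from the pre-degraded LR with exactly aligned HR windows
  (HR window = scale × LR window), avoiding per-crop resampling bias.
* **Crops.** 64×64 LR crops by default, 48×48 at scale 3.
* **Augmentation.** Random 90° rotations only (k ∈ {0..3}, same k for LR
  and HR) — no flips, matching the stated recipe.
* **Tiling.** `tile_image()` cuts HR patches into a non-overlapping
  row-major grid, e.g. 64 tiles of 128 from a 1024×1024 patch, the
  geometry used to feed SR outputs to a downstream classifier.
* **8-bit I/O.** PNG values map to [0,1] by /255; writing quantizes with
  round-half-away-from-zero.

## Dataset curation

`bcsr_build()` reproduces the published curation recipe on a directory of
extracted 1024×1024 patches (whole-slide parsing and coordinate sampling
are out of scope — the builder starts from PNGs):

1. **Blank filter.** Convert to 8-bit grayscale with BT.601 luma
   (the recipe does not name a formula; BT.601 is the field default),
   call a pixel white iff gray > 224 (i.e. 225–255), and *remove* images
   with more than 60% white area — exactly 60% survives.
2. **Distance ranking.** Compute each survivor's RGB mean `R_i` and the
   pixel-weighted global mean `R_all` *over survivors*; rank by
   `‖R_i − R_all‖₂` descending (ties broken lexicographically by path)
   and keep the top 1,200. This pushes the selected set toward maximal
   color diversity, forcing a model to train on wider, more critical
   regions.
3. **Split.** A seeded shuffle assigns 1,000 train / 200 test. The
   published recipe does not state how its split was drawn; the seeded
   shuffle is recorded in `provenance.json` so any build is exactly
   reproducible — the whole pipeline is a pure function of (file listing,
   config, seed), and rebuilds are byte-identical.

Per-image means are computed on raw pixels (no stain normalization first);
the recipe is silent on this and raw pixels are the simplest faithful
reading.

## Training

ADAM (β₁ = 0.9, β₂ = 0.999, ε = 1e-8 — pinned explicitly, since the
recipe does not state them) with the published schedule: learning rate
1e-4 halved after every 2×10⁵ updates
(`lr_schedule(u) = lr_init · 0.5^⌊u / halve_every⌋`). Batch size defaults
to 16 (unstated in the recipe; the common SISR default) and the total
update count is user-set. Checkpoints store parameters, optimizer
moments, the update counter and the RNG state, so `carn_train(resume =)`
continues bit-exactly: an interrupted run and an uninterrupted one
produce identical parameters and logs. Replicate reporting averages
metrics over the seed set {1, 7, 11, 18, 1011}
(`multi_seed_benchmark()`).

## The synthetic fixture generator

`generate_patch()` emulates what the modules need from stained tissue —
not its biology: a rank-uniformized multi-octave value-noise field blends
two stain colors placed symmetrically around the target channel means
(0.72, 0.43, 0.64), so the expected tissue mean equals the target by
construction; dark elliptical "nuclei" and fine speckle supply genuine
high-frequency content (Laplacian energy is asserted in tests); and an
optional contiguous wavy-edged white band occupies an exact pixel count,
so builder thresholds can be exercised with known ground truth. Every
patch is a pure function of (seed, index).

What the fixtures do *not* emulate: real stain variation between slides,
optical blur, scanner noise, and diagnostic structure. Tests passing on
fixtures therefore demonstrate that the machinery — degradation,
optimization, curation, metrics — is correct and that the network can
learn the inverse of the degradation on tissue-like statistics; they say
nothing about clinical image quality.

## The desk-scale benchmark

`sr_fixture_benchmark()` is the package's end-to-end learning check, sized
for a single CPU: a tiny model (2 CARBs, 16 channels, scale 2) trained
2,000 updates on 32 fixtures of 96×96, evaluated against bicubic
upsampling on 8 held-out fixtures. The scaled run uses 24×24 LR crops,
batch 4, and a constant 1e-3 learning rate — two orders of magnitude
fewer updates than a real training warrants a proportionally larger rate,
and the 2×10⁵-update halving schedule never triggers at this length. The
quantity of interest is the PSNR *gap* over bicubic on held-out images,
the scaled-down analogue of the full benchmark's CARN-versus-bicubic
margin; the training-loss curve is also required to be non-increasing in
500-update averages.

## Known limitations

* The exact block-internal composition of the reference architecture is
  under-specified; with the minimal two-convolution reading the parameter
  total does not reach the published 1.389 M budget. `convs_per_block`
  lets users explore deeper trunks; the package reports, not asserts, its
  budget.
* Published headline benchmark numbers (e.g. 40.358 dB / 0.9842 SSIM at
  2×) require the original curated slide dataset and GPU-scale training
  of multiple models; they are out of scope by design and nothing in the
  package claims them.
* Training runs on one CPU thread through hand-written backpropagation;
  it is meant for correctness, small studies and the desk-scale
  benchmark, not production-scale training.
* Only bicubic degradation is modeled — no JPEG artifacts, noise or blur.
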