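---
title: "Denoising paired low-dose CT: model, metrics and study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising paired low-dose CT: model, metrics and study statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdenoise)
```

`ctdenoise` implements a complete paired-dose CT denoising study in R: a
convolutional encoder–decoder network with DnCNN-style refinement, a
synthetic phantom generator that stands in for paired high/low-dose scans,
six paired image-quality metrics, circular-ROI Hounsfield-unit (HU) noise
analysis, and the reader-study statistics used to report observer scores.
This vignette explains the models and the design decisions; it states no
empirical result that the package's tests and scripts do not themselves
compute.

## The denoising network

The network maps a one-channel 8-bit slice to a one-channel slice of the
same size:

* **Encoder** — two stages of 3×3 convolution + ReLU + 2×2 max-pooling
  (stride 2), with 64 and 96 filters by default. Because of the two pooling
  stages, input dimensions must be divisible by 4.
* **Bottleneck** — a 3×3 convolution to 112 channels, ReLU, dropout.
* **Decoder** — two ×2 transposed-convolution stages (2×2 kernels, stride 2,
  96 channels). Each upsampled map is concatenated with the matching
  encoder stage's pre-pool features (a U-Net-style skip connection) and
  passed through a 3×3 convolution + ReLU.
* **Refinement head** — a stack of DnCNN-style blocks at full resolution,
  each `conv → batch norm → ReLU → dropout` (4 blocks by default).
* **Reconstruction** — a final 3×3 convolution with a single filter. By
  default the network predicts the image directly;
  `use_global_residual = TRUE` switches to predicting a correction added to
  the input, the classical residual formulation of DnCNN.

Design points that were genuinely open and how they were settled:

* *Encoder widths.* Descriptions of this architecture family disagree
  between a per-stage plan (64, 96) and a single encoder width (96); the
  default follows the two-stage plan since it is the more detailed
  statement, and a single integer passed to `denoiser_config()` expands to
  two equal stages so the other reading stays reachable.
* *Skip mechanism.* Channel concatenation (rather than addition) followed
  by a convolution, matching the U-Net lineage the architecture cites.
* *Refinement block granularity.* One convolution per block, with the
  block count configurable; a "two convolutions" reading is constructible
  by doubling `n_dncnn_blocks`.
* *Initialization.* He-uniform for convolutions (the standard choice under
  ReLU), batch-norm scale 1 / shift 0; fully deterministic given the seed.
* *Optimizer.* Adam with default moments; only the learning rate is
  exposed. MSE between the network output and the high-dose reference is
  the training loss, with best-on-validation checkpointing over a fixed
  epoch count.

All layers — convolution (im2col + BLAS), transposed convolution, max
pooling, batch normalization, dropout — are implemented in vectorized R
with exact analytic gradients; the test suite checks every gradient against
central finite differences and every kernel against brute-force loop
oracles.

A note on the configured learning rate: the reference configuration prints
0.003 even though its own fine-tuning interval was 1e-5 to 1e-4. The
package keeps 0.003 as the documented default; at the small channel counts
used in the tests it is also the rate that converges within a 10-epoch
budget.

## The synthetic phantom

Real paired-dose data cannot ship with the package, so the generator
emulates its statistical structure:

* **Geometry** — a soft-tissue disk (0 HU) on an air background
  (−1000 HU) carrying five elliptical organ-like regions whose mean HU are
  typical low-dose in-vivo levels: vitreous 18.75, brain 45.50, liver
  59.00, spleen 54.61, muscle 52.12. Ellipse edges give the structural
  metrics (SSIM, EPI, VIF) something to measure.
* **Noise** — additive i.i.d. Gaussian noise in HU whose SD follows the
  quantum-noise heuristic σ(f) = σ_full/√f for dose fraction f. The
  default σ_full = 13.5 HU puts low-dose in-organ SDs near the 17–26 HU
  range at the typical ≈55% dose reduction. Per-patient dose reductions
  are drawn uniformly from 41–83% (fraction f = 1 − reduction), one per
  patient, or can be supplied explicitly to replay a known protocol.
* **Texture** — within-organ variation is i.i.d. Gaussian
  (`texture_sd`, default 3 HU), so each organ's pixel mean converges to
  its target HU.

What the phantom is *not*: a CT physics simulator. There is no sinogram
domain, no beam hardening, no streak or structured noise, no anatomical
realism. Passing tests on phantoms therefore demonstrate that the pipeline
is correct and that the network can learn to suppress stationary Gaussian
noise — they say nothing about performance on real scanner noise, which is
spatially correlated and object-dependent.

## Hounsfield units and the 8-bit domain

The network consumes 8-bit arrays. The mapping from HU is an explicit
linear window (default: soft-tissue, center 40 HU, width 400 HU), rounded
half-up and clipped; the window is stored on every 8-bit image so the
mapping is invertible up to clipping and quantization, and so ROI analysis
always runs in HU, never on 8-bit values. Whether a fixed window or
per-volume scaling was used upstream in the reference work is unknowable;
the fixed window is the package default and both are expressible since the
window is a plain argument.

DICOM input/output is deliberately minimal — single-frame, uncompressed,
explicit-VR little-endian, honoring RescaleSlope/RescaleIntercept,
Rows/Columns, PixelSpacing, PatientID and InstanceNumber — because no R
DICOM package is available in the package's dependency footprint. Pixel
coordinates throughout the package are 1-based (row, col) with pixel
centers on integer coordinates, the native R convention.

## Quality metrics

Six paired metrics are computed on the 8-bit domain (L = 255) by default:

* **MSE** `(1/mn) Σ (a−b)²` and **PSNR** `10 log10(L²/MSE)` (identical
  images give an `Inf` sentinel, serialized as `"inf"`).
* **SSIM** in two modes. The *global* mode is the single-statistic formula
  `((2μxμy+C1)(2σxy+C2)) / ((μx²+μy²+C1)(σx²+σy²+C2))` evaluated once over
  the whole image with population moments — the literal printed formula.
  The *windowed* mode (default for reports) averages the same statistic
  over sliding 11×11 Gaussian windows (σ = 1.5), the variant whose scale
  matches commonly reported SSIM values.
* **VIF** as the pixel-domain multi-scale realization of the
  information-ratio quotient: at each of 4 scales, local Gaussian-window
  statistics define a gain-plus-noise channel, and the mutual-information
  terms of the distorted and reference channels are accumulated with a
  fixed visual-noise variance (2.0) in both. The full wavelet-domain GSM
  formulation is out of scope; the pixel-domain form is the standard
  desk-computable realization and equals 1 at identity.
* **EPI** in two modes. The *ratio* mode is the literal quotient of summed
  squared gradient differences over summed squared reference gradients
  (forward differences, edge-replicated) — note it is 0, not 1, for
  perfect preservation. Because reported edge-preservation values near 1
  are only consistent with a correlation-type index, the *correlation*
  mode (default for reports) is the normalized cross-correlation of the
  two gradient-magnitude images. Both are available and reports label the
  mode; neither is silently altered.
* **NV** the population variance of a single image, exactly as printed —
  computed on each arm's image, not on difference images.

MSE/PSNR/SSIM are symmetric in their arguments; VIF and EPI are
reference-anchored and deliberately not symmetric. ROI statistics use the
sample SD (n−1); NV uses the population form as printed — at ROI sizes of
hundreds of pixels the distinction is numerically irrelevant.

## ROI noise analysis

Circular ROIs are defined by a physical radius (default 8 mm) and placed by
pixel-center inclusion: a pixel belongs to the ROI iff its center lies
within the radius, which makes the mask an exact, testable lattice count
(an 8 mm circle on 1 mm isotropic spacing contains exactly 197 pixels) and
an ellipse in pixel space under anisotropic spacing. Area-weighted masks
were rejected for testability. The percent noise reduction between arms is
`100 (SD_LQ − SD_out)/SD_LQ`. Organ localization is manual in the source
study, so ROI placement is user-supplied; the phantom exports per-organ
canonical centers to make the five-organ analysis scriptable.

## Reader-study statistics

Observer studies report per-question summaries (mean, SD, median, IQR of
six 1–5 Likert scores), not raw scores. `reconstruct_scores()` inverts the
summaries exhaustively: all `choose(n+4, 4)` multisets of n scores are
enumerated and the unique multiset whose mean, sample SD, median and IQR
(linear interpolation of order statistics, the R type-7 default) round
half-up to the printed values is returned; zero or multiple matches raise
errors rather than guessing. The downstream statistics are the one-sample
two-sided t-test against the neutral midpoint 3, Cohen's d
`(mean − 3)/SD`, the standard error and the 95% CI half-width
`t₀.₉₇₅,ₙ₋₁ · SD/√n` ("CI width" in the conventional table layout).

Holm adjustment deserves a note. Published tables of this kind are often
computed with a tie-handling convention in which tied raw p-values receive
the *mean* of their group's step-down multipliers and no monotonicity
enforcement is applied; that variant is required to reproduce such tables
exactly and is what `analyze_reader_study()` uses by default
(`holm_ties = "average"`). Textbook step-down Holm–Bonferroni — sort,
multiply by k−rank+1, enforce monotonicity, cap at 1 — is available as
`holm_ties = "standard"` and is the `holm_adjust()` default. The two agree
whenever there are no ties among the raw p-values.

## Problem sizes used by the tests

The test suite trains end to end on a synthetic study of 23 patients × 10
slices at 64×64 pixels, split 15/4/4 by patient, with factor-4 paired
augmentation (rotations within ±10°, flips at probability 0.5 applied
identically to both arms), 10 epochs of batch-6 Adam at the default
learning rate 0.003 — and requires the denoised test arm to beat the
low-dose arm on both mean PSNR and mean SSIM. The desk-scale channel plan
for that run is encoder (6, 8), bottleneck 10, decoder 8, two refinement
blocks, dropout 0.1, direct image prediction (the default; the
global-residual variant converges to the identity at these widths and
epoch budgets). The full-size default configuration is
exercised separately for its architectural contract (a 512×512 slice maps
to 512×512; the parameter count equals the closed-form layer sum).

## Known limitations

* The phantom's stationary Gaussian noise understates the difficulty of
  real low-dose CT noise; metric improvements on phantoms are a necessary,
  not sufficient, indication.
* The hyperparameter search is a seeded random search (with exhaustive
  enumeration of small finite grids), not a model-based TPE optimizer; the
  search spaces are the documented tuning spaces.
* The DICOM layer reads only what it writes plus straightforward
  single-frame files; it is not a general DICOM implementation.
* Training is CPU-bound vectorized R: suitable for desk-scale studies and
  testing, not for full-resolution clinical training runs.
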