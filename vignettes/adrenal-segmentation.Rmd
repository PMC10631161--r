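---
title: "Volumetric adrenal-tumor segmentation: model, phantoms, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric adrenal-tumor segmentation: model, phantoms, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adrenalseg)
```

## The problem

Adrenal tumors occupy on the order of 0.267% of the voxels of an abdominal
CT volume. At that imbalance, per-voxel cross-entropy is dominated by the
background and a segmentation network happily predicts "no tumor"
everywhere; overlap-based losses and metrics are the standard response.
This package implements a complete, desk-scale pipeline for the task: a 3D
encoder–decoder network with depthwise separable convolutions and a
transformer bottleneck, trained with the soft Dice loss on randomly
positioned slabs of consecutive axial slices, evaluated with
Dice/IoU/Hausdorff/ASD/MAE, and compared across variants with a
Levene-then-t procedure. Because the clinical cohorts this class of model
is trained on are private, the package's data source is a synthetic
phantom generator whose stated targets mirror the cohort the design comes
from: 10 mm minimum lesion long axis, roughly 27% bilateral cases
(49 of 182), and the 0.267% mean tumor volume fraction.

## Preprocessing

Images pass through three steps, in a fixed order:

1. **Windowing** to level 40, width 300 HU — values clipped to
   [-110, 190] HU, the soft-tissue range relevant to adrenal lesions.
2. **Resampling** — in-plane grid scaled by 0.5 (spacing doubled),
   z-axis resampled to 1 mm using separable Keys cubic convolution
   (a = -0.5); masks use nearest-neighbour so they stay binary. The
   output z grid follows the grid-point convention
   `n_out = round((n_in - 1) s_in / s_out) + 1`: a 512×512×101 volume at
   (0.7, 0.7, 1.5) mm becomes 256×256×151 at (1.4, 1.4, 1.0) mm.
3. **Normalization** — min–max against the *fixed window bounds* (not the
   per-volume range), mapping [-110, 190] to [0, 1].

Two of these are genuine design choices rather than givens: the
normalization reference (fixed window bounds keep intensities comparable
across cases; a per-volume min–max would not) and the z grid-point
convention (the alternative `round(n·s_in/s_out)` differs by one slice;
either is defensible, one had to be fixed). Windowing is idempotent and
normalization is monotone; both are property-tested.

## The network

Feature maps are `[X, Y, Z, C]` arrays. The building block is a DSConv
unit: depthwise 3³ convolution (zero 'same' padding), pointwise 1³
convolution, group normalization (groups of at most 8 channels — batch
size 2 makes batch statistics unreliable), ReLU. Convolutions carry no
bias; the normalization shift makes one redundant.

* **Encoder**: a stem unit (1 → 16 channels at full resolution), then four
  stages of two DSConv units followed by a *learned* stride-2 depthwise
  downsampling (a 2×2×2 weighted pooling per channel). Channels double per
  stage: 32, 64, 128, 256 = C′. The pre-downsampling map of each stage is
  kept as a skip connection. The stem widths are the unique doubling chain
  of length 4 that ends at the printed bottleneck width C′ = 256.
* **Bottleneck**: with input (W, H, D) the bottleneck is
  C′ × W/16 × H/16 × D/16. One pointwise projection, then the *channel-token*
  reshape: C′ = 256 tokens, each a flattened spatial map of dimension
  N = (W/16)(H/16)(D/16) — 256 × 512 at the canonical 256×256×32 input.
  A learnable positional embedding (256 × N) is added. Four pre-norm
  transformer layers follow: `x + MHA(LN(x))`, `x + FFN(LN(x))`, with
  8 attention heads (`d_k = d_v = N/8`, an even split — the head
  dimensions are not printed anywhere, so symmetry is assumed), FFN hidden
  width 4N with GELU, and dropout (default 0.1) on each sublayer output
  during training.
* **Decoder**: the token sequence is reshaped back to the bottleneck grid
  ("feature mapping"), then four stride-2 transposed convolutions
  (kernel 2, non-overlapping) halve channels and double spatial dims; the
  corresponding encoder map is concatenated (when skips are enabled) and a
  DSConv unit fuses the pair. A pointwise head plus sigmoid yields
  foreground probabilities on the input grid.

The channel-token layout deserves a note: treating each *channel* as one
token (sequence length 256, embedding dimension N) is unusual — spatial
tokens are the common choice — but it is the literal published layout and
is implemented exactly so. Both the attention formula and the layer stack
are verified against term-by-term brute-force evaluation in the tests, and
the whole backward pass (written by hand; no autodiff framework exists in
this R stack) is verified against central finite differences at every
parameter group.

Ablation switches remove the transformer (`use_transformer = FALSE`; the
projection, positional embedding and layers disappear from the parameter
tree) and/or the skip connections, reproducing the component rows of the
reference ablation table; transformer depth is configurable over
2/4/6/8 layers.

## Training

Soft Dice loss `1 − (2Σpg + ε)/(Σp + Σg + ε)` with ε = 1e-5; Adam
(β₁ = 0.9, β₂ = 0.999) with L2 weight decay 1e-5 added to the gradient;
batch size 2; random 32-slice slabs (volumes shorter than the slab are
zero-padded symmetrically, the extra slice below); one slab per case per
epoch; case-level 80/20 split; seed 1000 drives every stream (split, slab
positions, dropout, and by convention the weight initialization).

The published schedule gives only two endpoints — 2e-4 at epoch 0 and
4e-7 at epoch 999. A multiplicative (log-linear) interpolation is the
natural way to traverse three orders of magnitude smoothly and is the
default; linear and cosine schedules are provided. The endpoints are exact
by construction.

**Scaled-down training runs.** The reference training is 1000 epochs on a
146-case training set (≈ 73k optimization steps) on four GPUs. The
package's tests and acceptance script train tiny configurations (stem 8,
64×64×16 slabs, a few hundred steps) on miniature phantom cohorts. At a
few hundred steps the published learning rate is far from any optimum —
it was tuned for 73k steps — so the scaled-down experiments use a
proportionally larger rate (1e-2 decaying to ~5e-4) with the same
schedule shape. The package defaults remain the published values; the
scaled rate is an explicit argument in the test and acceptance
configurations.

## Inference

Whole volumes are tiled along z into slabs of the training depth with a
configurable overlap; the final slab is end-aligned rather than
zero-padded, so no synthetic slices enter the network, and overlapping
predictions are averaged. Binarization is strict-greater at 0.5: a tie
goes to background, consistent with the 0.267% foreground prior. No
post-processing (connected-component filtering, morphology) is applied —
none is described for the reference method.

## Metrics

Dice and IoU by exact voxel counting (both-empty comparisons score 1);
MAE as the mislabeled-voxel fraction over the full grid (the reported
magnitudes ≈ 5e-4 only make sense on binarized predictions at a ~0.267%
tumor fraction — a probability-input variant would inflate it);
Hausdorff as the full symmetric max-min distance (not the 95th
percentile); ASD *directed*, prediction surface → truth surface, exactly
as the defining sum is printed — most toolkits symmetrize, so the
symmetric variant exists behind a flag but is off by default. Surfaces
are 6-connectivity boundary voxels (a foreground voxel with a background
6-neighbour, out-of-grid counting as background), with centers in
physical mm by default and voxel units as an option; the reference tables
never state their units, so no claim is made to reproduce them. Empty
masks make the surface metrics undefined (NA with a warning) while the
overlap metrics are still returned.

## Statistics

Levene's test in its classical mean-centred form (the unqualified name
means mean centring; median centring would be Brown–Forsythe), then a
two-sample t-test: pooled-variance Student when Levene does not reject at
α = 0.05, Welch otherwise — the natural reading of "check homogeneity,
then test". Unpaired by default (whether the reference comparisons were
paired is unstated); a paired option exists. Boxplot summaries use
linearly interpolated quartiles (type 7) and Tukey 1.5·IQR whiskers.

## The phantom generator

Each case composites, on a W×H×D grid (default 96×96 with D uniform on
40–100 slices at 1×1×1.5 mm):

* soft-tissue background at 40 HU,
* two kidney-like ellipsoidal organs at 100 HU placed symmetrically about
  the mid-sagittal plane,
* one or two tumor ellipsoids at 70 ± 15 HU placed superomedially to the
  organ poles (mirror-symmetric when bilateral), with a heterogeneous
  interior (white noise smoothed at 2 mm correlation length),
* a 1.5 mm Gaussian contour blur over the composited image,
* additive Gaussian acquisition noise, sd 12 HU.

The ground-truth mask is the *unblurred* analytic ellipsoid interior.
Cohort sampling draws laterality (bilateral probability 49/182), a slice
count, and per-tumor semi-axes whose total volume targets the 0.267%
fraction with mild lognormal jitter and anisotropy, scaled up if needed to
respect the 10 mm long-axis inclusion rule. Every case has its own RNG
stream derived from (seed, case index), so cohorts are reproducible and
order-independent.

None of the intensity choices is a published fact — the source material
reports no HU distributions — they are artifact choices, fixed once:
moderate tumor/background contrast (30 HU against 12 HU noise) after the
40/300 window, and organs brighter than tumors so that intensity alone
cannot separate lesion from organ. What a green test on phantoms
establishes is therefore that the *pipeline* (shapes, gradients,
optimization, stitching, metrics) works end to end — not that the model
reaches clinical accuracy; phantoms lack true anatomy, partial-volume
texture, contrast-phase variability and pathology diversity.

## Numerical choices and degenerate inputs

* Normalization epsilon 1e-5 in group/layer norm; Dice ε = 1e-5.
* Softmax rows are max-shifted before exponentiation.
* ReLU kinks make finite-difference gradient checks exact only to ~1e-3
  at step 1e-5 (crossings), tightening to ~1e-7 at step 1e-6; the test
  uses the latter.
* Constant volumes normalize to a constant with a warning; empty masks
  make surface metrics NA; a probability of exactly the threshold maps to
  background; two empty masks have Dice = IoU = 1.
* Group-normalization group count is min(8, C); all configured widths are
  divisible.
* Resampling below 8 voxels on any axis is refused.

## Limitations

* Single-channel, single-class, sigmoid head; no multi-phase CT.
* No DICOM ingestion — NIfTI-1 only, with a minimal reader/writer
  (3D images, common scalar datatypes, pixdim spacing, gzip).
* The canonical 256×256×32 configuration is structurally verified
  (shapes, parameter counts) but routinely trained only at reduced size
  on CPU.
* Baseline architectures from the comparison literature (3D U-Net,
  TransBTS, ...) are out of scope; the untrained network serves as the
  comparison partner in the acceptance run's statistics demo.
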