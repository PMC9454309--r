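---
title: "Methods: shifted-window CBCT-to-CT translation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shifted-window CBCT-to-CT translation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic phantom does and
does not emulate, the numerical choices, and the design decisions taken
where the design was genuinely open.

## The task and the model

Cone-beam CT (CBCT) slices carry systematic intensity errors — cupping from
scatter, streaks from photon starvation, a dark beam-hardening band between
dense bones, noise, and a global HU offset — that make them unreliable for
contouring and dose calculation. The package learns a slice-wise mapping
from CBCT to a synthetic CT (sCT) whose HU match a paired reference CT.

The translator is a U-shaped hierarchical encoder–decoder. The input
projection is a 3×3 convolution with LeakyReLU; four encoder levels each
run two transformer blocks and then a 4×4 stride-2 convolution that halves
resolution and doubles channels; a two-block bottleneck sits below; four
decoder levels mirror the encoders with 2×2 stride-2 transposed
convolutions, concatenation skip connections fused by a channel-reducing
linear map, and two blocks each; a 3×3 convolution projects back to one
channel. Attention is computed inside non-overlapping M×M token windows;
the second block of every level shifts the partition by ⌊M/2⌋, realized as
a cyclic shift plus an additive mask built from coordinate bands so that
softmax never mixes content that was not spatially adjacent before the
shift. Logits are `Q Kᵀ/√d + B` with a learned relative-position bias `B`
indexed by the 2D token offset, shared across windows, per head. The
feed-forward half of each block (LeFF) expands tokens with a linear layer,
re-grids them, applies a 3×3 depth-wise convolution, flattens, and shrinks
back, with exact GELU (`x·Φ(x)`) after every linear/convolutional layer.
Layer normalization acts over channels per token; both sublayers are
residual.

**Global residual.** By default the network's output is added to the input
CBCT, so the model learns an artifact *correction*. This was a genuinely
open design point; we chose the residual form for two reasons. First, the
task is residual by nature: the CBCT already carries the anatomy, and the
degradations are mostly low-frequency. Second, in desk-scale pilots the
non-residual variant improved mean absolute error but *worsened* PSNR —
with a small network and a short budget it blurs bone edges, and squared
error is edge-dominated, whereas the residual form preserves input edges
exactly at initialization. This is also the convention of the
shifted-window restoration lineage this architecture belongs to. Pure
synthesis remains available via `network_config(global_residual = FALSE)`.

Other conventions adopted where the design was open: attention logits are
scaled by 1/√d (the universal choice for this family; a plain 1/d scaling
is available as `attn_scale = "inv_d"` and differs only by a learnable
rescaling of the logits); the relative-position bias is a learned
(2M−1)²×k table; downsampling convolutions double the channel count
themselves; inputs whose sides do not divide 16·M are reflect-padded and
cropped back, so padding never enters the loss; skip fusion is
concatenation followed by a linear reduction.

## Parameters

| parameter | default | units / meaning |
|---|---|---|
| `base_channels` (C0) | 32 | channels after input projection; 4–8 for desk-scale runs |
| `window` (M) | 8 | attention window side, tokens; 4 for small images |
| `heads` | 1,2,4,8,16 | per level; channels must divide |
| `leff_expansion` | 4 | LeFF hidden-width ratio; 2 for desk-scale runs |
| `epsilon` | 1e-3 | Charbonnier constant, normalized intensity scale |
| `C1,C2,C3` | 1 | SSIM constants; large for [−1,1] images, kept configurable |
| `n_scales` | 3 | MS-SSIM dyadic scales for 128-px slices |
| `mix` | (0.9, 0.1) | Charbonnier : (1 − MS-SSIM) weights |
| `ssim_window` | 11 px (σ 1.5) | Gaussian local-statistics window |
| `learning_rate` | 0.001 | Adam, wrapped in Lookahead |
| `lookahead_k, alpha` | 5, 0.5 | slow-weight sync period and interpolation |
| `hu_range` | (−1000, 1000) | HU window mapped to [−1, 1]; bone above 1000 clips |
| `dose_criterion / dta` | 1% / 1 mm | gamma criteria, global normalization |
| `low_dose_threshold` | 0.10 | fraction of prescription below which voxels are skipped |
| `search_radius, step` | 3, 0.1 | gamma search radius (× dta) and candidate spacing (× dta) |

The network and optimizer defaults (M, C0, heads, depth multipliers, LeFF
expansion, Adam moments, Lookahead internals, the SSIM window) are
conventions of this architecture family, not values with an external
source; they are all exposed in the config objects.

## The loss

The objective is `0.9 · Charbonnier + 0.1 · (1 − MS-SSIM)`. Charbonnier is
the per-pixel mean of √((ŷ−y)² + ε²): the mean form keeps the ε-floor
scale-free and makes the ε→0 limit exactly the mean absolute error; a
per-image norm form is available (`charbonnier_form = "norm"`). The
similarity term enters as (1 − MS-SSIM) since the raw similarity must be
maximized. MS-SSIM multiplies mean contrast and structure terms over
dyadic scales (2× average pooling between scales) and the luminance term at
the coarsest scale only, with the standard 5-scale exponent vector
truncated to `n_scales` and renormalized. With C1 = C2 = C3 = 1 on
[−1, 1]-normalized images the SSIM terms are forgiving (the constants
dominate the tiny local variances), so the Charbonnier term carries most of
the training signal; the constants are configurable for users who want a
sharper structural term.

Numerical details: local variances are clamped at 0 before use; the product
σxσy is computed as √(varx·vary + 1e−24) so its gradient stays bounded when
one variance vanishes; per-scale means are clamped at 1e−8 before the
exponent so fractional powers never see a negative base. At ŷ = y the loss
sits at its floor 0.9·ε with an exactly zero, finite gradient.

## The synthetic phantom

`generate_anatomy()` draws a 2D analytic pelvis cartoon: an elliptical
body, two circular femoral-head bones, an elliptical bladder, and a rectum
disk with a gas pocket, at HU (air −1000, soft tissue 40, bladder 10,
rectal gas −800, bone 700), plus a seeded smooth texture (sd 5 HU) inside
the body; the background is exactly 0, matching the paired-data convention
in which everything outside the patient is zeroed. `degrade_to_cbct()`
adds, inside the body only: a cupping bias `−c·(1 − (r/R)²)` (most negative
at the body center, the sign real scatter produces), seeded straight
streaks through bone-interior points with a Gaussian cross-profile (σ 1.5
px, alternating dark/bright), a dark Gaussian band on the chord between the
two bones, white noise, and a constant HU shift. Defaults (cupping 40,
6 streaks at 30 HU, beam hardening 30, noise 10, shift 25) were set once to
put the raw-CBCT error burden in the tens-of-HU range a clinical pelvis
CBCT shows; the cupping and shift partially cancel in the mean, which is
incidental and harmless since the network sees the full spatial pattern.

What the phantom does *not* emulate — and hence what passing tests do not
show about clinical data: projection-domain physics (artifacts are painted
in image space), anatomical variability and deformable-registration
residuals between CT and CBCT, 3D context across slices, scanner-specific
noise correlation, and HU calibration drift. Efficacy on the phantom
demonstrates that the architecture, loss, optimizer and evaluation stack
are wired correctly and can learn this class of corrections; it is not a
claim of clinical performance.

`perturb_mask()` provides predicted-contour stand-ins (bounded
dilate/erode with seeded boundary jitter) so the contour metrics can be
exercised; `make_dose_pair()` provides a Gaussian-bell reference dose
peaking exactly at the prescription on a voxel, with the evaluated dose a
(1+δ) scaling, so gamma behavior has closed forms.

## Training and inference

Slices are clipped to `hu_range` and mapped affinely to [−1, 1], with
out-of-body pixels set to 0 HU first; training and validation share this
one preprocessing and loss code path. Adam updates fast weights each step;
every k-th step the slow weights move by α toward the fast weights and the
fast weights reset (Lookahead). Gradients flow through a package-internal
reverse-mode tape whose every operator is finite-difference tested;
batches are accumulated per sample. All randomness (initialization, batch
order, phantom content) derives from explicit integer seeds, and
checkpoints round-trip bitwise. `synthesize()` runs slice-wise, denormalizes
back to HU and re-zeroes the background using the supplied body mask, or a
mask estimated by thresholding at −300 HU, keeping the largest connected
component and filling holes — note the estimate presumes an air (≈−1000 HU)
background as acquired in-room; on images whose background is already
zeroed, supply the mask explicitly.

## Evaluation stack

MAE, RMSE and PSNR are computed over an explicit evaluation mask — for
paired body images the body mask (the union convention for two differing
masks), configurable to the whole grid. `max_p` defaults to 2000, the width
of the default HU window, since "the largest possible value" is a
convention; a per-image maximum is one argument away. PSNR of a perfect
match is reported as +Inf. ROI statistics use the population sd (the ROI
is the population of interest); report aggregation across cases uses the
sample sd (cases are a sample). DSC of two empty masks is defined as 1.
MDA is the symmetric mean surface distance with boundaries extracted as a
mask minus its 4-neighbour erosion, spacing-aware in mm.

Gamma analysis is global: the dose-difference criterion is a percent of the
prescription, voxels below 10% of the prescription are excluded, candidate
points within `search_radius`·dta (default 3) are scanned at a spacing of
`step`·dta (default 0.1) with trilinear interpolation of the evaluated
dose, and γ = 1 counts as passing. The implementation sorts candidates by
distance and stops once the spatial term alone exceeds the current best, so
it is exactly equivalent to the exhaustive scan — an equality the tests
assert against an independent full-grid oracle on a 16³ cube (with a
reduced radius/step so the pure-R oracle stays fast; both engines take the
same config, so the contract is parameter-free).

## Problem sizes used by the tests

The tests exercise the full pipeline at sizes a laptop CPU handles in
minutes, as the package's own study conditions: unit tests use 32–64 px
phantoms and a 2-channel network; the overfit check trains an 8-channel,
window-4 network on four 64-px pairs for 200 steps (composite loss falls
below 0.01); the efficacy check trains a 4-channel, window-4,
expansion-2 network for 2000 steps on ~200 synthetic 128-px pairs and
verifies that held-out MAE decreases and PSNR increases relative to the raw
CBCT. Directions, not magnitudes, are asserted: desk-scale magnitudes have
no reason to match any clinical report.

At desk scale the contour metrics must be read with the organ size in
mind: the Dice coefficient of a fixed millimetre-scale boundary
perturbation falls as the object shrinks (boundary-to-area ratio), so the
few-pixel phantom organs yield DSC values well below what the same
millimetre agreement produces on a clinical pelvis, while the MDA (a
boundary quantity, ~1.5 mm for the default 2-px perturbation) stays in the
clinically familiar range. The perturbed-contour stand-ins measure the
metric stack, not any segmentation method.

## Known limitations

2D slice-wise only (no volumetric attention or inter-slice consistency);
CPU double precision (no GPU kernels); the phantom's limits above; MDA is
defined for 2D contours; dose grids must share a grid (no resampling); and
the training loop is single-device with best-validation selection as its
only schedule.
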