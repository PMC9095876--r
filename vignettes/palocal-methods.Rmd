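---
title: "Methods: deep-learning-accelerated localization photoacoustic imaging"
author: "palocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep-learning-accelerated localization photoacoustic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The imaging model

Localization photoacoustic imaging exploits the temporal sparsity of point
absorbers flowing through vessels.  Each regular frame is a
diffraction-limited snapshot: point sources convolved with the system
point-spread function (PSF) plus noise.  Two absorbers closer than roughly
one PSF width are unresolvable in any single frame, but because they rarely
occupy the same neighborhood at the same instant, their *localizations* —
sub-pixel centroid estimates from different frames — can be superimposed
into an image whose resolution is set by localization precision rather than
diffraction.  The price is acquisition time: a dense reconstruction needs N
frames (OR-PAM, label-free red blood cells) or N detected droplets (PACT,
injected dye), while a sparse reconstruction from k ≪ N selections is fast
but undersampled.  The package's central claim, realized as a trainable
model, is that a conditional-GAN generator can map sparse reconstructions to
dense-quality ones, cutting acquisition 12-fold at the reference operating
points (60 → 5 frames; 240,000 → 20,000 droplets).

# The synthetic-data generator

Because no in vivo data ship with the package, every experiment runs on
synthetic phantoms with known ground truth:

* **Vessel trees** (`generateVesselTree`): straight cylindrical segments
  branching recursively (default bifurcation 2), radii and lengths shrinking
  geometrically with depth (factors 0.7 and 0.75), clamped to the region.
  This emulates the branching morphology of microvasculature at the scale
  the metrics see; it does not attempt physiological realism (no tortuosity,
  no anastomoses, no flow-dependent radii).
* **Flowing absorbers** (`sampleAbsorbers`): each absorber occupies a
  length-weighted random segment at a random axial fraction and radial
  offset strictly inside the lumen, and advances per frame by a uniform
  [0.5, 1.5] multiple of a mean speed (default 10 µm/frame), respawning when
  it leaves its segment.  Only the existence of inter-frame flow matters for
  the method; the kinematics are deliberately minimal.
* **Frame rendering** (`renderFrame`): separable Gaussian PSF, amplitude in
  (0, 1], constant background, additive Gaussian noise (default sd 0.02 of
  full scale), clipped to [0, 1].  OR-PAM defaults: 3.75/5 µm lateral pixels,
  3 µm axial pixel, 5 µm lateral FWHM (optical-diffraction scale) and 114 µm
  axial FWHM (the acoustic axial-resolution scale).  PACT default: 25 µm
  pixels, 125 µm FWHM, so the 5 µm superresolution grid (factor 5) refines
  the pixel area 25-fold.
* **Absorber density** is not prescribed by the physics; the default of 25
  per 64 × 64 frame keeps single-frame detections mostly isolated (the
  regime localization requires) while filling the tree over tens of frames.

What passing tests on these phantoms demonstrate: the geometry of the
pipeline (localization precision, superposition, resolution beyond the PSF),
the correctness of losses/metrics/gradients, and that the learning problem
is solvable end-to-end.  What they do not demonstrate: performance on real
tissue, where speckle, absorber polydispersity, motion artifacts and depth-
dependent fluence are absent from the simulator.

# Localization operator

The in-package operator (`localizeFrame`) is a stand-in with the standard
input/output contract of localization microscopy: difference-of-Gaussians
band-pass (sigmas 1 and 2 px), strict local maxima above an amplitude
threshold, greedy minimum-separation pruning (strongest first), and
intensity-weighted centroid refinement in an odd window (default 7 px).  On
noise-free blobs the mean centroid error is well under 0.2 px (tested), and
it degrades gracefully with noise.  Superpositions are rendered by
nearest-pixel deposition (`rasterizeEvents`) with "sum" accumulation for
PACT (droplet addition) and "max" for OR-PAM — the latter an explicit
package convention (the convention is not fixed by the physics; `mode` is a
switch) chosen to preserve per-vessel amplitude across many frames.  Sparse
selection operates on whole frames for OR-PAM and on individual droplets
for PACT.  For *training pairs*, localization images may additionally be
rendered with a small Gaussian (default 1 px) — the standard practice of
drawing each localization with its precision — which stabilizes the
structural-similarity losses on otherwise near-binary dot fields.

# Metrics

`psnr`, `ssim`, `msSSIM` are dimension-agnostic (2D/3D).  SSIM uses the
standard constants (11-point Gaussian window, sigma 1.5, k1 = 0.01,
k2 = 0.03, population covariance) and averages the local map where the
window fits entirely inside the image; the implementation was verified
against an independent reference implementation to 10 decimal places on
frozen fixtures.  MS-SSIM downsamples by 2× average pooling, scores
contrast/structure at every scale and full SSIM at the coarsest, combining
them as a weighted geometric mean with the canonical five-scale weights.
Feasibility note: an s-scale pyramid needs `floor(dim / 2^(s-1)) >= 11` on
every axis, so 64-pixel images support 3 scales; the auto-selection clamps
with a notice, while an explicit infeasible request errors, naming the
maximum.  Weights are renormalized to sum to one when clamped.  Singleton
axes are dropped so 3D calls reduce exactly to 2D on depth-1 volumes.
Negative contrast terms are floored at 1e-8 before exponentiation (they can
only arise on anticorrelated inputs, where the score's magnitude is already
meaningless).

# Networks

Both generators share one U-Net plan (`GeneratorSpec`): `levels = 4` encoder
blocks of two 3 × 3 feature convolutions (leaky rectifier 0.2), 2× max-pool
between levels, a mirrored decoder, long skips by channel concatenation, and
one output convolution squashed by a sigmoid onto [0, 1], the range of
normalized amplitudes.
That accounting gives 2·4·2 + 1 = 17 feature convolutions; the four
upsampling operators are parameterized separately.  Short skips sum a
stride-1 3-window max-pooled copy of each block input into the block output
(channel-truncated or zero-padded as needed) — max-pooling in the residual
branch emphasizes local maxima, the objects localization imaging cares
about.  Upsampling is a transposed convolution in 3D, realized exactly as a
1 × 1 × 1 convolution to 8·C channels followed by channel-to-space
rearrangement (the two are algebraically identical for kernel 2, stride 2),
and a sub-pixel (pixel-shuffle) convolution in 2D, where transposed
convolutions produce checkerboard artifacts.  The 3D generator takes two
input channels (sparse localization + regular volume) and keeps per-channel
feature normalization and spatial dropout (0.2); the 2D generator takes the
sparse image alone and omits both.  Channel widths double from a base of 64
(capped at 512) in 3D and 120 (uncapped) in 2D; these bases were chosen so
the defaults land near the architecture's reference parameter scales (≈46 M
and ≈104 M trainable parameters; the discriminators carry ≈4.7 M and
≈1.6 M).  Since per-layer width tables are not available, the totals are
treated as soft anchors, not exact targets.  Discriminators are patch-wise:
four stride-2 leaky-rectifier convolutions and a sigmoid output convolution
(five convolutional layers), producing a probability map whose mean enters
the losses.  Weights are He-normal initialized (seeded), with one
deliberate exception: the closing convolution of each generator residual
block starts at zero, so every block initially passes its max-pool shortcut
through unchanged — the zero-gamma practice of residual networks.  Without
it, feature magnitudes amplify through the additive short skips and
concatenated long skips until the output sigmoid saturates into a constant
dark state for an appreciable fraction of initialization seeds; with it,
every probed seed trains smoothly.

The batch-normalization gap: the engine processes samples singly
(gradients accumulate over the batch), so the 3D "batch" normalization is
implemented as per-sample, per-channel spatial normalization with learned
gain and bias, identical at train and inference time.  This is the
deterministic member of the normalization family and the natural choice at
batch size 1; it is the package's own design decision where the source
architecture tables are unavailable.

# Training

`fitGAN` alternates one discriminator and one generator update per batch,
with Adam (defaults: learning rate 2e-4, betas 0.5/0.999, L2 1e-5 — the
recipe states a grid search without printing values, so these are the
pix2pix-lineage standards), probabilities clamped to [1e-7, 1 − 1e-7]
before logarithms, and full seeding of initialization, shuffling,
augmentation and dropout.  Augmentation applies the identical random crop
and x/y flips (p = 0.5) to input and target.  After every epoch the
validation MS-SSIM is recorded and the best epoch's weights become the
checkpoint.  The scale count of the MS-SSIM used inside a run is pinned
once, from the training crop size, so the loss is identically configured
across epochs.  Divergence (non-finite loss) aborts with a condition object
carrying the partial record.  `transferFinetune` implements the 2D
schedule: pre-training with the MAE + MS-SSIM loss, then fine-tuning with
the full adversarial loss against a freshly initialized discriminator; the
returned record documents the loss-function switch.

## Desk-scale study conditions

Full-scale training (200 epochs, thousands of 64³ pairs, ~43 M-parameter
3D networks on GPUs) is a cluster-scale undertaking, so the
package defines explicit desk-scale conditions used by its experiments and
tests (`sparseToDenseExperiment`): 64 training + 16 held-out 2D pairs of
64 × 64 pixels at the 60 → 5 frame operating point, a base-8 two-level
generator (~30 k parameters), random 32 × 32 crops, learning rate 1e-3,
batch 4, and the full transfer schedule — 35 pre-training epochs on an
OR-PAM maximum-amplitude-projection-style corpus (frame-wise selection,
max accumulation) followed by 15 adversarial fine-tuning epochs on the
PACT-style corpus (droplet-wise, sum accumulation) — over three training
seeds.  Besides being the schedule the method prescribes, pre-training on
the brighter MAP-style domain stabilizes optimization: trained cold on the
dark, sparse PACT images, some seeds collapse to a constant dark output (a
recognized failure mode of structural-similarity + MAE objectives on
mostly-empty scenes).
The success criterion is ordinal, not absolute: the generator's held-out
MS-SSIM against the dense target must exceed the sparse input's, for a
majority of seeds — the same ordering the full-scale studies report, at a
scale where the in vivo numbers themselves are not reproducible.
`sparsitySweep` establishes the companion mechanism: MS-SSIM of sparse
reconstructions rises monotonically in k (positive Spearman correlation
across selection seeds).

# Numerical choices and degenerate inputs

* Coordinates are physical micrometers with the origin at the grid corner;
  array positions are 0-based grid units with pixel centers at integers.
* PSNR of identical images returns `Inf` flagged with a `zeroMSE`
  attribute rather than erroring: zero MSE is a meaningful sentinel.
* `depthEncode` breaks ties toward the smallest axial index.
* Local-maxima detection resolves plateaus toward the lexicographically
  smallest index (strict comparison backward, non-strict forward).
* Bicubic resampling (axial 4× downsampling; 2000 × 2400 → 896 × 1024
  resizing) uses a Catmull-Rom kernel stretched by the scale factor for
  antialiasing, edge-replicated boundaries and row-normalized weights, so
  constants are exactly preserved and sub-Nyquist sinusoids keep their
  amplitude within 2 % (tested against the analytic resampling).  It is
  hand-written because no installed R routine offers bicubic-with-
  antialiasing semantics.
* TIFF output stores 32-bit samples quantized on [0, 1] (error < 2.4e-10);
  NIfTI stores doubles bit-exactly and carries voxel sizes.  Dataset
  bundles are directories with a JSON manifest plus NIfTI/TIFF arrays —
  an open, inspectable layout whose provenance block suffices to
  regenerate the bundle bit-identically.
* Generator inputs must be divisible by 2^levels; the error names the
  required divisibility.  Empty frames localize to empty event sets, not
  errors; events outside the grid are skipped with a warning.

# Known limitations

* The simulator omits speckle, scanner jitter, depth-dependent fluence and
  acoustic reconstruction artifacts; conclusions transfer to real data only
  as far as those effects preserve the sparse-to-dense mapping's structure.
* The localization operator is a generic detector, not a reimplementation
  of any scanner-specific pipeline; absolute localization precision on real
  radio-frequency data is out of scope.
* The engine is CPU-bound and single-sample; full-scale 3D training is
  intentionally out of scope, and the 3D path is exercised at smoke-test
  scale (shape contracts, gradient checks, one-step loss decrease).
* MS-SSIM on near-binary dot images is brittle; the 1 px rendering sigma in
  pair construction is a declared convention, and results should be read
  relative to the sparse baseline computed under the same rendering.
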