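---
title: "Patient-realistic phantoms by unpaired style transfer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-realistic phantoms by unpaired style transfer: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomForge)
```

## The problem

Digital anthropomorphic phantoms are piecewise-constant: every organ is a
region of one CT number (or one MRI intensity), so their histograms are
discrete and their images are noise-free. Models trained on real patient
images — continuous-valued, noisy, textured — cannot be validated
meaningfully against such phantoms, because the domain gap inflates error
metrics regardless of model quality. phantomForge closes this gap by
*style transfer*: an unpaired image-to-image translation network maps
phantom slices into the patient image domain while preserving the known
anatomy, yielding perfectly aligned multimodal (CT + MRI) volumes with
patient-like statistics that can serve as ground truth for cross-modality
synthesis models (for example, synthetic-CT-from-MRI networks used in
MRI-only radiotherapy workflows).

## The model

Two generator/discriminator pairs form a CycleGAN per modality. The
generator `G_XY` maps phantom patches to patient-like patches, `F_YX`
maps back; PatchGAN discriminators `D_X`, `D_Y` score local realism in
each domain. The generator objective for the phantom-to-patient direction
is the weighted sum

$$L(G_{XY}) = L_{GAN}(XY) + \lambda_{cyc}\,[L_{cyc}(XY) + L_{cyc}(YX)]
  + \lambda_{int}\,L_{int}(XY) + \lambda_{gdl}\,L_{gdl}(XY)$$

with

* **adversarial** term $-\log D_Y(G_{XY}(x))$, binary cross-entropy
  against the "real" target (mean over the discriminator's output map);
* **cycle consistency** (mean L1 between an image and its
  there-and-back reconstruction, summed over both directions) to pin the
  translation to the input anatomy;
* **intensity** term (mean L1 between the input and its translation) to
  keep organ intensities near their phantom values;
* **gradient difference** term penalizing squared discrepancies between
  the absolute forward-difference gradients of input and output along
  rows and columns, preserving tissue boundaries. It is invariant to
  constant offsets by construction.

Discriminators minimize half the sum of the two BCE terms
($\tfrac12[\mathrm{BCE}(1, D(y)) + \mathrm{BCE}(0, D(\hat y))]$); the
fixed factor 2 slows the discriminator relative to the generator. They
are fed a randomly selected image from a buffer of the last
$K = 50$ generated images rather than always the newest one, which
stabilizes adversarial training.

Architectures: the generators are ResNet-style — a 7×7 stem, two
stride-2 downsampling convolutions, nine residual blocks at full scale,
and two bilinear-upsample + convolution decoder blocks — with reflection
padding everywhere (to avoid boundary artifacts), instance
normalization, and a tanh head. Bilinear (not transposed-conv)
upsampling avoids checkerboard artifacts. The discriminators are 70×70
PatchGANs: five 4×4 convolutions with strides 2, 2, 2, 1, 1 and padding
1, which maps a 256×256 input to a 30×30 sigmoid map whose units each
see a 70×70 receptive field. Both facts are recomputed by the test
suite and the acceptance script from the actual layer stack.

### Why these fixed hyper-parameters

The cycle weight (10), adversarial weight (1) and generator learning
rate (2e-4) are the standard unpaired-translation settings and are held
fixed. The tunable parameters are the two auxiliary loss weights and
the discriminator learning rate; the shipped working points are
`ganConfigCT()` ($\lambda_{int} = \lambda_{gdl} = 1$, LR_d = 2e-5 — a
faster discriminator was found to overpower the generator on CT) and
`ganConfigMRI()` ($\lambda_{int} = \lambda_{gdl} = 0.5$, LR_d = 2e-4).
Adam uses $\beta_1 = 0.5$, $\beta_2 = 0.999$ (the GAN convention;
momentum 0.9 is too aggressive under adversarial non-stationarity) and a
constant learning rate. All $\log$ terms are clamped at
$\varepsilon = 10^{-7}$.

### The network engine

No deep-learning framework is part of this package's dependency set; the
convolutional engine is implemented in R directly: convolutions run as
cached-index im2col gathers followed by BLAS matrix products, the data
gradient is the transposed convolution of the stride-dilated output
gradient with the flipped kernel, instance normalization and all
activations carry analytic backward passes, and bilinear resizing is
expressed as separable interpolation matrices so that its adjoint (needed
for backpropagation through the decoder) is exactly a transpose. Every
backward pass is verified against central finite differences in the test
suite. Training is bit-reproducible for a given seed.

## The data pipeline

**Geometry.** Volumes are arrays ordered (slice, row, col) with explicit
mm spacing. In-plane resampling targets a new pixel spacing; the output
size is `round(size * oldSpacing / newSpacing)` with halves away from
zero — a 370-pixel plane at 1 mm becomes 348 pixels at 1.0625 mm, the
geometry in which all tiling below operates.

**CT preparation.** Clip to [-1000, +1047] HU; build a body mask per
slice (threshold at -110 HU, fill holes, close boundary leaks along the
Sobel edge band, keep the largest connected component); set the
background to -1000 HU; rescale linearly to [-1, 1]. MRI uses its
per-volume (min, max) for the rescale, recorded so the inverse is exact.
The Sobel "edge refinement" step of the masking chain is
under-specified in the field's usual description; here it is the Sobel
gradient magnitude of the binary mask, dilated by one pixel and
re-filled (then eroded back and unioned with the filled mask), which
closes single-pixel boundary leaks without growing the outline.
Hysteresis
thresholds of the separate Canny edge detector (used by the edge
metrics) are fractions (10%/20%) of the gradient-magnitude maximum — a
definition that is robust on arbitrary intensity scales; both fractions
are configurable and recorded in every report.

**Patches.** Training patches (220 px for CT/phantom at strides 32/64,
200 px at stride 32 for MRI at full scale) are drawn per slice from the
stride lattice of origins, with a clamped final origin whenever the
lattice misses the right/bottom edge; this same rule makes inference
tiling of a 348×348 slice produce exactly nine 220×220 patches that
cover it exactly (128 + 220 = 348). Four random patches per slice are
kept for training (uniform, without replacement, seeded); an optional
foreground filter (≥ 20% of the patch inside the body mask, off by
default) suppresses background-dominated candidates. Patches are resized
bilinearly to the 256×256 network input and predictions are resized back
to the native patch size *before* fusion — positions are only valid in
native geometry. Fused output pixels are the mean of all covering
patches; with pass-through predictions fusion inverts tiling bit-exactly,
and through the 220↔256 resize cycle the reconstruction error is ≤ 2%
RMS on band-limited images.

## The synthetic phantom generator

Licensed NURBS anatomy libraries are out of scope, so the package ships
a parametric abdominal generator that reproduces the *properties* the
pipeline depends on: a body ellipse containing lungs, liver, spine,
aorta and bowel as analytic ellipsoids/tubes; piecewise-constant CT
renderings via per-tissue attenuation coefficients at 120 keV
(`HU = 1000 (μ - μ_water)/μ_water`, with μ_water = 0.1615 cm⁻¹ by
default — only the ratio matters, and the value is configurable in the
tissue-table header); and MRI renderings via a per-tissue intensity
lookup emulating T1-weighted gradient-echo (VIBE-like) contrast rather
than sequence physics. CT and MRI from one label volume are voxelwise
co-registered by construction — the property that makes the generated
pairs usable as cross-modality ground truth.

The "patient" domain is emulated by degradations: stationary correlated
Gaussian noise (Gaussian-filtered white noise rescaled to a target SD),
a smooth multiplicative bias field, and optional per-organ texture. The
defaults — 20 HU noise with 1.5-voxel correlation for CT, 9 a.u. for
MRI, 5% bias — sit at the noise levels measured in abdominal patient
scans (liver noise magnitude ≈ 21.5 HU for CT, ≈ 8.7 a.u. for MRI).
What the generator does *not* emulate: beam hardening, scatter, MRI
k-space artifacts, respiratory motion, lesions. Tests passing on these
phantoms therefore demonstrate the correctness of the machinery and the
learnability of simple domain gaps, not clinical-grade realism.

## Evaluation machinery

**Paired** (generated vs its own clean phantom, slice-wise, then
averaged as mean ± SD): MAE; SSIM (11×11 Gaussian window, σ = 1.5,
K1 = 0.01, K2 = 0.03, valid-window averaging; data range fixed at 2047
for CT, per-volume for MRI); FSIM (log-Gabor phase congruency, 4 scales
× 4 orientations, noise compensation, Scharr gradients, T1 = 0.85,
T2 = 160 on an internal 0–255 rescale); Canny-based EPR (preserved
original edge pixels / original edge pixels) and EGR (generated edge
pixels / original edge pixels); PSNR, Pearson NCC, RMSE; and LPIPS
through a pluggable backend only — no pretrained feature-network weights
are shipped, so without a user-supplied backend the field is reported as
unavailable rather than failing. Slices whose original edge map is empty
are excluded from the EPR/EGR averages and counted in the report.
A perfect SSIM is *not* the goal of style transfer — the translation is
supposed to change texture; the paired metrics bound structural
distortion rather than demand identity.

**Unpaired** (generated cohort vs patient cohort): liver noise magnitude
(population SD within the organ mask); the radially averaged noise power
spectrum of a 64×64×20 ROI (per-slice mean subtraction, 2D FFT,
`Δx·Δy/(NxNy)` scaling, equal-width annular bins — absolute scale is
irrelevant because only Pearson correlations of curves are compared);
and HistCC, the Pearson correlation between cohort-mean intensity
histograms (fixed 10-HU bins over the CT clip window; 128 bins on the
pooled range otherwise; body-only histograms available via masks).

**Dosimetry**: empirical cumulative DVH curves over masked voxels (equal
voxel weights, no partial-volume interpolation — this matches the verbal
definition of the summaries exactly), with D95% for targets (largest
dose received by at least 95% of the volume, higher-value tie
convention) and D2% for organs at risk. Plan comparisons report
recalculated-minus-reference differences; relative errors use the
prescribed dose as denominator for targets and the reference plan's own
metric for organs at risk. Dose *calculation* is out of scope — the
module consumes dose grids computed elsewhere.

## Numerical choices and degenerate inputs

* Resize/resample interpolation aligns pixel-center grids
  (`(i + 0.5)·nIn/nOut − 0.5`), so same-size resizing is the exact
  identity and constant images are invariant.
* Denormalization clamps to [-1, 1] first: tanh outputs can overshoot
  only by floating-point noise, and clamping keeps CT outputs inside
  [-1000, 1047] by construction.
* Degenerate intensity ranges (max = min) are errors, not silent no-ops.
* Empty body-mask slices are legal (all-air slices occur at volume
  ends); empty original edge maps make EPR/EGR undefined and are
  excluded from averages; zero-variance inputs make NCC undefined and
  raise an error rather than returning 0.
* The discriminator requires at least 16 input pixels (below that the
  five-conv stack produces no output map); inputs smaller than its 70-px
  receptive field are allowed for desk-scale work, the map is then
  simply coarser than one full field.
* Tie-breaks in D_p% take the higher dose, matching "minimum dose that
  p% receives".

## Desk-scale study sizes

The test suite and examples run the whole machinery at reduced size:
generators with 1 residual block and 8 base filters on 64×64 patches, 16
phantom + 16 patient-like patches, 30 epochs for the learning smoke
check (cycle loss must at least halve; a large intensity weight must
pull `G(x)` toward `x`). The full-scale configuration (9 blocks, 64
filters, 256×256, 150 epochs, thousands of patches) is expressed by the
same code and `ganConfig()` defaults but is a GPU-scale undertaking and
is not exercised by the tests.

## Known limitations

Hand-written training on CPU is orders of magnitude slower than a GPU
framework; the engine exists to make the method fully inspectable and
dependency-free, not to reproduce full-scale training runs. The phantom
generator's anatomy is schematic (no NURBS surfaces, no pathology). The
MRI rendering is a contrast lookup, not sequence simulation. LPIPS
requires an external backend. DICOM series and RT-STRUCT inputs are not
parsed — volumes enter as NIfTI or MetaImage.
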