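---
title: "Virtual H&E staining from FLIM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual H&E staining from FLIM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimstain)
```

## The problem

Fluorescence lifetime imaging microscopy (FLIM) records, for every
pixel of an unstained tissue section, two quantities: the photon-count
intensity of the endogenous autofluorescence and the fitted decay time
(lifetime, in nanoseconds) of that fluorescence. Lifetime is
intensity-independent and sensitive to the molecular microenvironment,
which makes FLIM attractive for label-free tissue characterisation —
but FLIM images are hard to interpret at the cellular level without a
histological reference, and a matching H&E section is rarely available
alongside them.

`flimstain` implements a complete computational bridge: it converts
FLIM exports into network-ready representations, co-registers them with
bright-field H&E scans of the same sections, trains a conditional
image-to-image translation network to synthesise virtual H&E directly
from FLIM, scores the synthesis against real staining with standard
full-reference metrics, and — once a virtual H&E exists as a reference
— extracts per-cell lifetime signatures from annotation masks.
A deterministic tissue-phantom generator provides paired data so that
every stage runs, and is tested, without instrument data.

## Input representations

Raw exports are clamped once to fixed display ranges, `[0, 2000]`
photon counts and `[0, 5]` ns, and intensity is normalised globally per
cohort (per TMA core), never per patch, so relative brightness between
fields survives. Three candidate network inputs are built
(`make_intensity_input()`, `make_alpha_flim()`, `make_iw_flim()`):

* **intensity** — `1 - I_norm`, a single channel with tissue dark on a
  white background, mimicking bright-field contrast;
* **α-FLIM** — lifetime false-coloured over a *fixed* `[1, 5]` ns
  window and the normalised intensity appended as a fourth (alpha)
  channel;
* **IW-FLIM** — the same false-colour image with each channel
  multiplied pixelwise by normalised intensity.

The fixed colour window means lifetimes below 1 ns saturate at the
first colour-table entry; we clamp rather than extrapolate, so tissues
with unusually short lifetimes still map into the table. The shipped
colour table is a perceptually ordered blue→green→red 256-entry lookup
generated from fixed anchors (`flim_colormap()`); any 256×3 CSV table
can be substituted. By construction the two FLIM formats satisfy an
exact algebraic identity — IW-FLIM equals α-FLIM's RGB multiplied by
its alpha channel — which the test suite asserts to 1e-12.

## Co-registration and patching

H&E scans arrive at a finer pixel size than FLIM (e.g. 0.22 µm vs
0.455 µm) and are resampled to the FLIM grid with Keys bicubic
interpolation (`downsample_he()`). For registration the H&E is reduced
to luminance and contrast-stretched so its 1st/99th percentiles span
`[0, 1]`; the FLIM side contributes inverted normalised intensity.
`estimate_affine()` then maximises normalised mutual information
(32-bin joint histogram) over a 3-level image pyramid: a deterministic
grid search over translations and rotations at the coarsest level seeds
a Nelder-Mead refinement of the full 6-parameter pose (translation,
rotation, two log-scales, shear), which is propagated down the
pyramid. Everything is deterministic; with phantom ground truth the
recovered transforms land well under one pixel of mean corner error
for poses up to ±15°, ±20 px and 10% scale. A least-squares
control-point mode is available as a fallback for degenerate content.

Co-registered pairs are cut into fixed patches (256 px reference
geometry; 64 px in the desk profile) on a regular grid. A pixel is
called background when its normalised intensity falls below 0.05 —
signal-free regions carry essentially no photons; the threshold is
configurable, and the filter is computed on the FLIM side since that is
the side whose signal the network consumes. Patches with strictly more
than 75% background are discarded; a patch at exactly 75% is retained.

## The translation network

The generator is a U-Net operating on whole patches: `levels` stride-2
4×4 convolutions double features while halving resolution; the decoder
mirrors them with a 1×1 channel-halving projection, nearest-neighbour
upsampling and a 3×3 convolution, with skip connections at every level;
the output head is `(tanh + 1)/2`, bounding virtual H&E in `[0, 1]`.
Bottleneck dropout (0.5) is active during training and is the model's
stochasticity source — the generator is conditioned on the FLIM input
alone. The discriminator is a patch-based classifier over the candidate
H&E concatenated with the conditioning input: two stride-2
convolutions and a 3×3 head produce a grid of realism scores, so each
score judges a local receptive field rather than the whole image.

The discriminator is trained with the standard conditional
cross-entropy (real images labelled 1, synthetic 0); its printed
published form with the two terms exchanged would reward a
discriminator for calling fakes real and cannot train, so the standard
orientation is used. The generator minimises

```
alpha * L_adv + beta * L1 + lambda * DISTS,    alpha = 0.1, beta = 1, lambda = 5,
```

with Adam (`beta1 = 0.5`, `beta2 = 0.999`) and a step-decay schedule
(initial 1e-4 divided by 10 every 60 epochs, 300 epochs in the
reference profile). Both networks' adversarial terms are scaled by
`alpha`. D and G gradients are taken simultaneously from a single
discriminator pass over the synthetic batch and the two Adam updates
applied together. Augmentation is horizontal flipping plus rotations
drawn uniformly from ±15°.

## The DISTS term

The perceptual term compares images through a feature hierarchy: stage
0 is the image itself, deeper stages are convolutional feature maps.
For each map, a texture term compares global means,
`(2 μ_r μ_s + c1) / (μ_r² + μ_s² + c1)`, and a structure term compares
global (co)variances, `(2 σ_rs + c2) / (σ_r² + σ_s² + c2)`; DISTS is
one minus the weighted sum over all maps. Weights are non-negative and
sum to one (the published constraint "sum to zero" is impossible for
non-negative learnable weights and is read as the usual normalisation);
uniform weights are the default, and externally trained weights can be
loaded from JSON. `c1 = c2 = 1e-6` are pure numerical guards. With the
normalisation, identical images score exactly 0 and the value is
bounded by 2 (by 1 when no structure term goes negative).

Because no pretrained backbone can be assumed, the default extractor is
a VGG16-topology stack (five stages, 64–512 channels) with fixed,
orthogonally initialised weights generated from a pinned seed — fully
deterministic and offline. Random-feature extractors retain the
metric's identity, symmetry, boundedness and blur-monotonicity
properties, which is what the correctness tests exercise; they are not
a perceptual calibration, and retraining the weights on quality-rated
image sets is explicitly out of scope. The loss is differentiable in
the synthetic image; the analytic gradient is verified against finite
differences to 1e-4 relative error, and a hand-rolled
means/covariances oracle pins the value to 1e-10 on a tiny fixed
extractor.

## Evaluation metrics

Four full-reference metrics with pinned conventions
(`nrmse()`, `nmi()`, `psnr()`, `mssim()`):

* NRMSE: Euclidean error normalised by the reference norm (lower
  better). This normalisation is chosen because reported tissue-scale
  values (~0.09–0.13) are consistent with it.
* NMI: `(H1 + H2) / H12` over 256-bin histograms of the greyscale
  images, in `[1, 2]`; larger means more similar — the bolded best
  values in the published comparison table are the largest, and the
  information-theoretic reading agrees, so the table footnote calling
  smaller NMI better is treated as an erratum.
* PSNR: `10 log10(1 / MSE)` dB on unit-range images; identical images
  report `Inf`.
* MSSIM: mean SSIM over interior 11×11 Gaussian windows (σ = 1.5,
  K1 = 0.01, K2 = 0.03, data range 1), channels scored separately and
  averaged.

`compare_formats()` ranks input formats per metric with the orientation
handled (lower-better NRMSE, higher-better otherwise) and ties flagged.

## Lifetime signatures

Given a label mask of annotated cells, per-cell lifetime histograms are
tallied over `[0, 5]` ns with 0.05 ns bins *centred on multiples of the
bin width*, so a cell whose pixels all read 2.0 ns reports a peak of
exactly 2.0 ns. Two summaries are reported because both are in use in
the field: the peak (modal bin centre, ties broken toward the shorter
lifetime for determinism) and the pixel-weighted mean. Cells of a type
are pooled pixel-weighted; the per-type table is sorted by ascending
mean lifetime and per-cell signatures are attached for dispersion
analysis.

## The phantom generator

Phantoms emulate a TMA core: a circular tissue disc (radius 0.48 of the
short image edge) filled with autofluorescent stroma (Poisson mean 150
counts; lifetime N(0.45, 0.1) ns, a short collagen-like value), in
which seven cell types are embedded as non-overlapping nucleus +
cytoplasm-halo discs placed by rejection sampling. Default per-type
mean lifetimes are published per-type values (0.251 ns for red blood
cells up to 2.42 ns for macrophages) with σ = 0.05 ns, so phantom
demonstrations echo real tumour-microenvironment biology; brightness
makes macrophages bright and RBCs dim, matching their visibility in
real intensity images. Photon counts are Poisson throughout (mean =
variance, which the tests check); background outside the disc is a
20-count Poisson floor.

The H&E rendering is driven by geometry alone: nuclei get haematoxylin
optical density 1.0 (plus a little eosin), cytoplasm eosin 0.45, stroma
eosin 0.25, and the RGB image is `exp(-OD_h·c_h - OD_e·c_e)` with the
standard haematoxylin/eosin absorbance vectors — background renders
exactly white. Because the rendering never sees lifetime or intensity,
a network cannot shortcut the task by copying channels; it must learn
the FLIM-to-stain mapping.

All randomness flows through R's Mersenne-Twister with pinned
normal/sample kinds and a caller-restored seed, so a spec plus seed
reproduces a phantom bit-for-bit; the identity is asserted in the
tests. What the phantom does *not* emulate: instrument response and
decay-fitting artefacts, multi-exponential lifetime mixtures within a
cell, chromatic aberration or staining variability between labs, and
tissue deformation between imaging and staining beyond an affine map.
Passing phantom tests therefore demonstrates the pipeline's mechanics
and the recoverability of its parameters, not clinical image quality.

## Problem sizes and the desk profile

The reference ("full") profile matches the published recipe — 256×256
patches, an 8-level 64-feature U-Net, 300 epochs — and is GPU-scale.
The shipped `desk` profile is the package's CPU-scale configuration
used by examples, tests and the acceptance script: 64×64 patches, a
3-level U-Net with 16 base features, batch 8, 20 epochs, a 2-stage
(8, 16) feature extractor for the DISTS term, and a 2e-3 learning rate
suited to the small network (the step-decay rule is unchanged). Under
this profile, training 128 phantom patches takes a couple of minutes on
one CPU and lifts held-out MSSIM from roughly 0.65 (untrained) to above
0.9; the acceptance checks require ≥ 0.6 with a gain of ≥ 0.2 in at
least 2 of 3 seeds, which the suite verifies by running the training.

## Numerical and design choices

* Convolutions are im2col + GEMM with compiled kernels; all layer
  gradients, including the DISTS path, are finite-difference checked.
* FLIM rasters are written as uncompressed IEEE-float TIFFs by a
  minimal writer (`write_float_tiff()`), because no available writer
  emits true float samples; values live in native units and a
  read→write→read cycle is bit-exact. A JSON sidecar carries pixel
  size and clamp bounds; a two-page dialect (intensity, lifetime) is
  also read.
* Fit-failure (`NaN`) lifetime pixels become 0 ns and are counted on
  the returned object; 0 ns renders as background under the colour
  map.
* Whole-field inference pads with edge replication to the network's
  downsampling multiple and crops back, so arbitrary field sizes are
  stained without patch seams.
* Registration initialisation is an exhaustive coarse search, making
  the whole estimate deterministic; non-finite similarity aborts with
  the last value rather than returning a silent identity.
* Train/test splits are by field, never by patch, mirroring
  independent-section evaluation.

## Known limitations

The DISTS backbone is a fixed random-feature hierarchy unless
pretrained weights are supplied, so absolute DISTS values are not
comparable to published perceptual scores. The desk-scale model is far
below the reference capacity and is meant to validate the training
machinery, not to produce diagnostic-quality virtual stains. Published
tissue-level metric values and cell lifetimes cannot be reproduced
without the original (undeposited) tissue data; the package instead
verifies every recoverable property against phantom ground truth.
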