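---
title: "Lesion localization in the sinogram domain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion localization in the sinogram domain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Digital breast tomosynthesis (DBT) acquires projections of the breast over a
narrow angular arc and reconstructs quasi-3D slices from them. Reconstruction
is costly and introduces artifacts, yet most lesion-detection pipelines run
on the reconstructed images. The alternative explored here is to segment
lesions *before* reconstruction, directly in the sinogram: a localized mass
in the image appears in the sinogram as a smooth trace whose detector
position varies with the projection angle, so its location is recoverable
from projection data alone. The pipeline is:

1. map a 2D image and its binary lesion mask to sinograms with the
   parallel-beam Radon transform under a limited-angle geometry,
2. train a U-Net to segment the lesion trace in the (normalized, cropped,
   resized) image sinogram,
3. map the predicted sinogram mask back to the spatial domain by filtered
   backprojection (FBP) and measure how well the lesion *location* — not its
   exact shape — is recovered.

Because clinical mammography/DBT archives cannot be redistributed with a
package, a seeded synthetic phantom generator stands in for them; every
stage is exercised end-to-end on phantoms.

## Sinogram geometry and conventions

For an image $f(x,y)$ the Radon transform is
$$\mathcal{R}f(\theta, t) = \int f(t\cos\theta - s\sin\theta,\;
t\sin\theta + s\cos\theta)\, ds,$$
the line integral at angle $\theta$ and signed detector offset $t$. Fixed
conventions, used consistently by the transform, FBP and every file format:

* sinogram **rows** index detector position $t$, **columns** index the
  angle; the angle set is the inclusive sequence $-25^\circ$ to $+25^\circ$
  in $2.5^\circ$ steps (21 projections) unless overridden;
* 0-based (row, col) pixel coordinates with pixel centers at integers and
  the rotation center at $((H-1)/2, (W-1)/2)$;
* the detector axis spans the image **diagonal** (odd number of unit bins),
  so no corner mass is discarded and the sum of every sinogram column equals
  the total image mass up to interpolation error (relative error well below
  1e-2, tested);
* integration samples the image bilinearly at half-pixel steps along each
  ray (`s_substeps = 2`). Finer substeps change results negligibly.

A note on an accuracy subtlety: projections of a *hard-edged* digital disk
are not exactly angle-invariant — the pixelized disk itself is not
rotationally symmetric, which limits any sampled Radon implementation to
roughly 1–3% column-to-column spread. For smooth radial profiles (e.g., a
Gaussian bump) the implementation is angle-invariant to ~1e-4. The test
suite asserts both regimes separately.

## Filtered backprojection

FBP filters each projection with the discrete Ram-Lak (ramp) kernel of Kak
& Slaney — applied by FFT with zero-padding to at least twice the detector
length, no apodization window — and smears the filtered projections back
along their directions:
$$\hat f(x,y) = \frac{\pi}{N_\theta} \sum_{\theta}
\check{\mathcal{R}}f(\theta,\; x'\cos\theta + y'\sin\theta).$$
The $\pi/N_\theta$ scale keeps intensities comparable across angle sets.
With the full half-turn of angles this pair nearly inverts (Pearson
$r > 0.99$ on a disk inside the inscribed circle, tested at $r \ge 0.95$);
with the $\pm25^\circ$ arc the reconstruction is strongly smeared along the
un-sampled directions, but the smear is symmetric about the true object, so
its thresholded centroid stays put — the quantitative core of the
localization claim. On oracle (ground-truth) mask sinograms at 256×256 the
median centroid error is bounded at 3 px in the tests.

Binarization of reconstructed masks (negative ringing clamped to zero
first) is a relative threshold at **0.2** of the maximum, with Otsu's method
available. The value was calibrated once on oracle mask sinograms — the
ground-truth trace passed straight to FBP, so no model is involved — across
both lesion regimes the generator produces. Limited-angle backprojection of
a lesion trace forms a broad plateau rather than a sharp peak, and the peak
is not centered on extended lesions: thresholding high (at half the
maximum) keeps only the peak and biases per-lesion centroids of extended
lesions by several pixels, while Otsu fails in the mirrored way,
over-including the smear wings of small lesions. A scan over relative
thresholds showed 0.2 to be accurate in both regimes; the test suite pins
the resulting guarantee (median oracle-mask centroid error at most 3 px at
256 px). Both the rule and the fraction are configurable.

## From sample to training pair

For each sample the image sinogram is min–max normalized to $[0,1]$ and the
mask sinogram — the Radon transform of the binary mask — is binarized at
**5% of its own maximum**. A strictly positive relative threshold is used
instead of "any nonzero value" because bilinear interpolation leaks tiny
positive values far from the true trace; 5% means a ray must intersect the
lesion for at least 5% of the longest chord to count. Both sinograms are
then cropped to the minimal detector-row band containing the mask trace
plus a 10-row margin (the lesion-focused extraction step; the crop window
is retained so predictions can be mapped back), resized bilinearly to the
128×128 model input, and the mask re-binarized at 0.5 after interpolation.

Three image sizes appear deliberately: 256 (spatial standardization before
the Radon transform), 128 (model input), and 224 (the frame whose diagonal
normalizes the localization percentages). All three are configuration keys;
their defaults reflect the sizes the evaluation mathematics is calibrated
to, and the 224 default makes the diagonal $D = 224\sqrt{2} \approx 316.78$
used by the overlap percentage.

## The network

A symmetric encoder–decoder with skip connections, built from scratch on
single-precision GEMM (im2col) kernels:

* **Encoder**: 4 blocks of [3×3 conv → batch-norm → ReLU] ×2, dropout
  $p = 0.2$, then 2×2 max-pool. Channel widths 32-64-128-256 (base width 32,
  doubling per level — the base is configurable; widths are not stated by
  the evaluation protocol and were chosen once for CPU-trainable capacity).
* **Bottleneck**: two more conv–BN–ReLU layers at 256 channels (8×8 for a
  128-px input).
* **Decoder**: 4 blocks of upsample (nearest-neighbor by default, matching
  "an upsampling step followed by a convolution"; bilinear available) →
  3×3 conv–BN–ReLU → concatenation with the encoder skip → merging 3×3
  conv–BN–ReLU → dropout. Batch norm is mirrored symmetrically in the
  decoder (its presence there is an open choice; symmetry was chosen).
* **Head**: 1×1 convolution + sigmoid, so outputs are probabilities.

Dropout sits at the end of every block, encoder and decoder symmetrically.
Batch norm uses batch statistics during training (momentum 0.1 running
estimates for inference) with $\epsilon = 10^{-5}$.

The loss is the hybrid objective
$$L = L_{\mathrm{BCE}} + (1 - \mathrm{Dice}_{\mathrm{soft}}),$$
with BCE the pixel mean of $-[G\log P + (1-G)\log(1-P)]$ (predictions
clamped to $[10^{-7}, 1-10^{-7}]$) and the soft Dice
$(2\sum P_iG_i + \epsilon)/(\sum P_i + \sum G_i + \epsilon)$ with
$\epsilon = 10^{-5}$, the same stabilizing constant the evaluation Dice
uses; two empty masks therefore agree at Dice 1. During training the Dice
term is averaged per image over the batch. Backpropagation through the
whole graph is verified against finite differences in the test suite.

## Training recipe

Adam with learning rate $10^{-4}$, L2 weight decay $10^{-6}$, batch size
16, a fixed learning rate (no schedule, no early stopping), and selection
of the epoch with the highest validation Dice. Whether the validation Dice
should be computed on thresholded masks or on the raw probabilities is an
open choice; this package uses the **soft** Dice of the probabilities.
The two estimate the same overlap, but at desk-scale validation sizes
(ten-odd images) the thresholded score is extremely noisy — it can swing
by twenty points between adjacent epochs and hand selection to an immature
early epoch — while the soft score ranks epochs consistently with held-out
behavior. Test-set evaluation still uses thresholded Dice/IoU.

The shipped end-to-end experiment (60 patients, two views each, the default
recipe at 30 epochs) is scored in the acceptance tests as test-set mean
sinogram Dice and the median per-lesion centroid distance after FBP on a
224-px frame; those tests, not this document, are the source of its
numbers. Augmentation applies, each with independent probability
0.5: joint rotation of image and mask by a uniform angle in $\pm15^\circ$
(mask re-binarized after interpolation), horizontal flip of both, and
additive Gaussian noise ($\sigma = 0.02$) on the image only. The
probability and noise level are package choices; the transform set and
rotation range are part of the protocol.

Splits are at the **patient** level: patients are shuffled by seed and
partitioned 70/15/15 (fractions configurable), so no patient's images ever
span subsets and both modalities of a patient travel together. The split,
augmentation, dropout and batch order all derive from one master seed
(per-stage seeds are hashes of the stage name), making runs bit-reproducible
on a deterministic BLAS; multi-threaded BLAS reductions may reorder sums,
which is the one documented caveat to exact replay.

## The phantom generator

Each phantom is an elliptical "breast" support (~40% of the frame) filled
with smooth low-frequency Gaussian-field texture that fades at the support
boundary. Lesions are hyperintense ellipses (masses) with a raised-cosine
radial falloff and an optional low-order harmonic boundary perturbation
(irregularity ≤ 0.2 keeps each mask component's centroid within 2 px of
its generating center, a tested invariant). DBT mode compresses in-support
contrast by 0.6 and adds Gaussian detector noise ($\sigma = 0.03$) — per
the construction order, the degradation is applied to the background
before lesions are inserted, and DBT lesion contrasts are additionally
scaled by the same 0.6 so DBT lesions are never more conspicuous than
mammography ones (also a tested invariant).

Dataset defaults — the study conditions for all shipped experiments — are
60 patients with two annotated 256-px views each (the craniocaudal /
mediolateral pair of a standard screening study), a DBT fraction of 0.2
(the ~1:4 ratio of annotated DBT to mammography images in the public
archives), 1–2 lesions per image with semi-axes 5–14 px, contrast
U(0.25, 0.55) and irregularity U(0, 0.2). Each sample draws its own RNG
stream from (seed, patient, image), so datasets are stable under
reordering and bit-identical across runs.

What the phantoms do **not** emulate: real parenchymal texture statistics,
microcalcifications, hypointense or spiculated lesions, volumetric DBT
stacks, scanner physics (scatter, dose, detector response), and the
lesion-size/contrast distributions of clinical archives (which are not
published at that granularity). Passing the synthetic-recovery tests
therefore demonstrates that the pipeline's machinery — transform pair,
network, optimization, inverse mapping, metrics — works end-to-end and
that sinogram-domain localization is learnable under controlled
conditions; it does not certify clinical performance.

## Evaluation mathematics

With $P$ the predicted and $G$ the reference binary mask:
Dice $= (2|P\cap G| + \epsilon)/(|P| + |G| + \epsilon)$, IoU
$= |P\cap G|/|P\cup G|$ (two empty masks agree at 1), and the exact
algebraic identity $\mathrm{IoU} = \mathrm{Dice}/(2-\mathrm{Dice})$, which
holds for every mask pair when both are computed from the same counts with
$\epsilon = 0$ — the test suite verifies it on all $2^9 \times 2^9$ pairs
of 3×3 masks.

Localization reduces masks to centroids (mean 0-based pixel coordinate of
the nonzero set; an empty mask is an explicit error, never a silent
origin), measures the Euclidean centroid distance $d$, and normalizes by
the image diagonal: $\mathrm{Overlap}(\%) = \max(0,\, 100\,(1 - d/D))$
with $D = \sqrt{H^2 + W^2}$. The cropped IoU restricts scoring to the
ground-truth lesion's bounding box expanded by a 10-px margin, so a distant
false positive in a large background does not dominate.

Multi-lesion images are scored per lesion: ground-truth lesions are the
8-connected components of $G$ (connectivity configurable), matched
one-to-one to predicted components by minimizing total centroid distance
(exhaustive enumeration up to 6 lesions, greedy beyond); unmatched lesions
are reported with zero overlap and cropped IoU and an explicitly undefined
predicted centroid. Reports are tibbles, serialized as CSV/JSON rounded to
2 decimals, matching the presentation precision of the evaluation tables.

Precision/recall "approximated from the Dice score" have no defined
formula in the protocol this package follows and are deliberately not
implemented.

## Numerical choices and degenerate inputs

* Mask-sinogram binarization threshold 0.05 × max (see above), model
  prediction threshold 0.5, reconstruction threshold 0.5 × max — all
  configurable.
* Min–max normalization treats a range below 1e-12 (relative) as constant:
  `sinogram_pair()` raises an error (a training pair without contrast is
  unusable), `normalize_resize()` warns and returns zeros (tolerable at
  inference).
* An all-zero predicted sinogram reconstructs to an all-zero mask without
  error; an empty ground-truth mask is always an error in metrics.
* Bilinear interpolation everywhere (Radon sampling, resizing, rotation);
  corner-aligned resize grids so a same-size resize is exact.
* Conv-bias gradients under batch norm are analytically zero; the biases
  are retained for architectural fidelity but are inert.
* Greedy/exhaustive matching tie-breaks: exhaustive enumeration prefers the
  first minimal assignment in row order; ties in distance are broken by
  enumeration order.

## Problem sizes in the shipped experiments

The package's own experiments (test suite and worked examples) use: 50
phantom sinograms at 128 px for conservation/linearity properties; 20
oracle-mask reconstructions at 256 px for the limited-angle localization
bound; an 8-pair overfit run at 64 px (base width 16, ≤ 120 epochs) as an
optimization sanity check; and the headline synthetic-recovery run — 60
patients at 256 px, the default recipe at 30 epochs, 128-px inputs, base
width 32 — reported as test-set mean sinogram Dice and median post-FBP
centroid error on a 224-px frame. These sizes keep the full suite on a
single CPU core while still spanning every stage at the fidelity the
evaluation mathematics assumes.

## Known limitations

* Sinograms are computed from (synthetic) reconstructed-style images, not
  raw scanner projections — the same compromise the underlying protocol
  makes, since commercial systems do not expose raw projections.
* Single-slice images only; no volumetric DBT stacks.
* The limited-angle centroid bound (3 px at 256 px) and the end-to-end
  recovery thresholds (Dice ≥ 0.6, ≤ 5 px at 224) are this package's
  acceptance calibration for synthetic data, not clinical figures.
* Training determinism is exact only on a deterministic BLAS.
* The network is CPU-oriented; no GPU path exists, which bounds practical
  problem sizes well below clinical-archive scale.
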