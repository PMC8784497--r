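---
title: "Hybrid multi-atlas and adversarial segmentation of the psoas major muscle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid multi-atlas and adversarial segmentation of the psoas major muscle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The volume of the bilateral psoas major muscle (PMMV, in cm^3) is an
opportunistic imaging marker: abdominal CT acquired for any indication also
depicts the psoas, and its volume proxies total skeletal muscle mass in
sarcopenia assessment. Manual slice-by-slice segmentation is slow, so
`pmmseg` implements an automated pipeline with three methods and a shared
evaluation harness:

* **GAN** — a 2.5D adversarial slice segmenter (U-Net generator, patch
  discriminator) that delineates muscle borders precisely but can
  hallucinate structures far from the psoas;
* **MAS** — multi-atlas segmentation by dual-stage deformable registration
  and strict-majority label fusion, globally robust but boundary-loose and
  volume-overestimating;
* **COM** — their combination: the MAS mask dilated by 2 pixels acts as a
  spatial gate that is intersected voxel-wise with the GAN mask, keeping
  the network's precise borders while discarding its distant false
  positives.

Because no public CT cohort accompanies this problem, the package ships a
seeded synthetic phantom generator that stands in for a clinical cohort in
every test; all empirical statements below are about those phantoms.

## Data model

Volumes are 3D Hounsfield-unit grids with voxel spacing and origin in mm
(`image_volume`); masks are boolean grids on the same lattice
(`binary_mask`, labelled left/right/bilateral). Arrays are stored in R's
column-major order with dimensions `(nx, ny, nz)`, so the x index is
fastest and `[, , z]` is the contiguous axial slice — the slice-major
layout the 2.5D sampler iterates over. NIfTI-1 is the interchange format
(masks as unsigned 8-bit 0/1; any nonzero reads back as foreground).
Volumes must have at least 3 slices, since the 2.5D sampler needs both
axial neighbours. A file without usable pixel dimensions is rejected
rather than assumed to be 1 mm. DICOM series input is not provided;
convert series to NIfTI first.

## The phantom generator

`generate_case()` builds a body-like ellipse of fat density (-90 HU) with
a midline bone column (400 HU) and two muscle-density tubes (55 HU,
SD 6 HU texture) flanking it — the psoas analogue. The tube radius tapers
parabolically to zero toward the first/last slices, mirroring how the
psoas does not reach the top and bottom of an abdominal exam; interior
slices therefore carry the muscle, and slice 1 and n are empty. Each case
draws a radius scale uniformly from `volume_scale_range` (default
0.8–1.2, i.e. a coefficient of variation of about 23% in volume,
comparable to an adult cohort), and is warped by a smooth random
displacement field (white noise smoothed at 14 mm, scaled to a 2.5 mm
pointwise SD) applied identically to image and mask — backward warping,
linear interpolation for the image, nearest-neighbour for the mask, so
the mask stays exactly the deformed tube support. Gaussian noise
(SD 12 HU) is added to the image only.

The desk grid is 64 x 64 x 24 voxels at (2, 2, 5) mm: the 5 mm slice
thickness of routine abdominal CT is kept, while the in-plane 512 x 512
clinical matrix is scaled down so a full cross-validated experiment runs
on a laptop. What the phantom does *not* emulate: surrounding organs,
contrast phases, HU calibration drift, pathology, and the inter-patient
anatomical variability of real abdomens. Passing tests on phantoms
therefore demonstrate the pipeline's mechanics and its comparative
behaviour (precision vs robustness vs their fusion), not clinical-grade
accuracy.

Seeding: a cohort draws all per-case seeds up-front from the master seed,
so case k is reproducible regardless of generation order.

## Multi-atlas segmentation

Each atlas (an annotated image/mask pair) is registered to the target in
two stages, both authored in the package:

1. **Affine stage** — 12-parameter affine transform about the volume
   centre, minimizing mean squared intensity error by preconditioned
   gradient descent over a coarse-to-fine pyramid (factors 8/4/2/1;
   levels whose downsampled grid would drop below 4 voxels on any axis
   are skipped). Each level is initialized from the previous one. The
   preconditioning scales matrix entries by the physical field of view so
   a unit step in any parameter moves points by comparable millimetres;
   the step length starts at `step_mm` (x the pyramid factor) and decays
   linearly to 10%.
2. **B-spline stage** — free-form deformation on a cubic B-spline control
   grid (default 20 mm knot spacing) added to the affine map, maximizing
   mutual information (32-bin joint histogram, cubic Parzen window on the
   moving intensity, hard binning of the fixed intensity). The metric and
   its analytic gradient are evaluated on a random voxel subsample
   (fraction 0.25, capped; drawn once per registration from the given
   seed) and optimized by gradient descent with a linearly decaying step.

The registration *energy* is the final value of the optimized metric:
negative mutual information after the B-spline stage (or the final MSE if
the deformable stage is disabled), a single lower-is-better scale.
`mas_segment()` registers all atlases, ranks them by energy with a
deterministic case-id tie-break, keeps the five best, and fuses their
propagated masks by strict-majority voting: a voxel is muscle iff it
appears in more than half the masks (3 of 5; an even split is excluded).
Mask propagation uses nearest-neighbour interpolation so labels stay
binary; images are interpolated linearly.

Numerical choices worth noting: the metric subsample is fixed per
registration rather than redrawn per iteration (cheaper, and makes the
converged energy a deterministic function of the seed); histogram bin
coordinates are clamped two bins from the edges so the Parzen window
never leaves the table; out-of-grid samples read as air (-1000 HU). On
the regular output grid the B-spline field is evaluated by separable
tensor contraction, which is algebraically identical to the pointwise
basis but far cheaper. A registration whose metric turns non-finite is
flagged failed, warned about, and excluded from ranking.

## The 2.5D adversarial segmenter

Each interior slice z (2 … n-1) becomes a training sample: channels are
slices z-1, z, z+1 (below/active/above), clipped to a soft-tissue window
of [-200, 300] HU, scaled to [-1, 1] and resized in-plane to
`train_size`; the label is resized with nearest-neighbour interpolation
so it stays strictly binary. The generator is a U-Net: stride-2 4x4
convolutions down, nearest-neighbour upsampling plus 3x3 convolutions and
skip concatenations up, instance normalization and leaky-ReLU after every
convolution except the sigmoid output head. The discriminator is a
3-layer patch classifier on the concatenated (image, mask) pair, emitting
a grid of per-patch real/fake probabilities. Depth defaults to
`log2(train_size) - 2` levels (4 at size 64), keeping a 4 x 4 bottleneck
rather than collapsing to 1 x 1, where instance statistics degenerate.

The loss is the classical adversarial objective plus a pixel L1 term
weighted 10:1 (`total = 1.0 * L_GAN + 10.0 * L_L1`): the adversarial term
demands plausible input–mask pairs, the L1 term pixel-level fidelity.
Both networks train with Adam (first-moment decay 0.5). The default
configuration (256 x 256 inputs, 50 epochs, learning rate 2e-4) is the
clinical-scale recipe; the *desk* configuration used by the experiment
harness is 64 x 64 inputs, batch size 1, learning rate 1e-3 and a handful
of epochs — at a few hundred optimizer steps instead of a few hundred
thousand, the higher rate is what makes training converge, and it was
fixed once from a single-case memorization calibration, not tuned against
cohort outcomes. The saturating log-form generator loss is the default,
with a non-saturating variant config-switchable; gradients flow through
the sigmoid in logit space, which keeps them bounded even when the
discriminator saturates.

Inference runs every slice: interior slices use their true neighbours,
slices 1 and n replicate the missing neighbour. Since the phantom (like
the psoas) keeps the muscle off the terminal slices, this padding choice
is volumetrically neutral, but it makes the contract total — every input
slice yields an output slice. Sigmoid outputs are thresholded at 0.5 and
resized back to the native grid with nearest-neighbour interpolation.
Training is repeatable for a fixed seed and configuration on one machine;
bit-identity across differing BLAS builds is not promised.

## Fusion

`combine_masks()` dilates the MAS mask and intersects it with the GAN
mask. Dilation is **2D in-plane**: a 3x3 4-connected cross applied
`radius_px` times (default 2), i.e. a city-block ball per slice. With
~1–2 mm in-plane pixels and 5 mm slices, an isotropic 3D element would
dilate anisotropically in physical space; a flag enables 3D dilation for
experimentation. The operator guarantees `COM ⊆ GAN` and
`COM ⊆ dilate(MAS)`, is monotone in both arguments, and removes every GAN
component disjoint from the dilated MAS support — the failure mode it
exists to fix.

## Evaluation harness

* Volume: voxel count x voxel volume, reported in cm^3.
* Overlap: Dice similarity coefficient `2|A∩B| / (|A|+|B|)`; two empty
  masks are defined to agree perfectly (DSC 1) — absence matched is
  agreement.
* Correlation: Spearman's rank correlation (mid-ranks under ties).
* Paired testing: Wilcoxon signed-rank, two-sided, zero differences
  dropped. For n ≤ 25 the null distribution of the positive-rank sum is
  computed exactly by convolution over doubled mid-ranks (exact even
  under ties); larger n uses the normal approximation with the standard
  tie correction. p < 0.05 is the significance convention.
* Median DSC confidence intervals: seeded nonparametric percentile
  bootstrap (10,000 resamples by default).
* `volume_error_stats()` reports the mean signed percentage error of
  cohort means, the mean squared difference (a squared-volume quantity,
  cm^6) and its root (cm^3) — both are labelled explicitly because a
  squared difference quoted in cm^3 is ambiguous.

`run_experiment()` performs fivefold cross-validation at patient level:
cases are shuffled with the experiment seed and partitioned 80/20
(larger folds first when the cohort size is not divisible by 5). Per
fold, the network trains and the atlas pool is drawn from training cases
only, so no test case is ever seen during training. Each test case is
segmented by GAN, MAS and COM; records carry per-case volume and Dice,
and the summary adds per-method medians with bootstrap CIs, Spearman
correlation of predicted vs true volumes, signed-rank p-values and
volume-error statistics.

The desk experiment (10 phantoms, fivefold) exists to reproduce the
*qualitative* cohort finding — the combined approach matches or beats
both parts in median Dice and is strictly closer in cohort volume than
the atlas pipeline — not any particular clinical number: with 10
synthetic cases, two test cases per fold and a scaled-down network, the
absolute values are not comparable to a 34-patient clinical cohort.

## Design choices that were genuinely open

* **Voting rule**: strict majority at n/2 (3 of 5) was chosen as the
  operationally defined fusion rule; energy-weighted alternatives would
  need weights nothing in the pipeline defines.
* **Energy across metrics**: the two stages optimize different metrics;
  ranking uses the last stage's converged value (negative MI), giving one
  lower-is-better scale.
* **Dilation element**: the 4-connected cross iterated to a city-block
  ball, in-plane. The element and its dimensionality are config-exposed.
* **dsc(∅,∅) = 1**: agreement on absence counts as perfect agreement.
* **Per-side vs bilateral**: left/right masks merge via `merge_lr()`
  (voxel-wise OR); all reported statistics are bilateral, per-side masks
  remain available.
* **Registration sampling**: a fixed, seeded subsample per registration
  trades a little stochastic-gradient freshness for determinism and
  ranking comparability.

## Problem sizes and limitations

The shipped experiment sizes — 10 cases of 64 x 64 x 24 voxels, fivefold
CV, 4 training epochs, 8-atlas pools with top-5 fusion — were chosen so
the complete suite runs on a single desktop core in well under half an
hour. Known limitations: the phantom's simplicity (two tubes in an
ellipse) makes both segmenters look better than they would clinically;
the registration optimizer is a fixed-step-schedule gradient descent, not
a full adaptive stochastic scheme; network training at desk scale uses a
few hundred updates and a learning rate chosen for that regime; and
determinism is per-machine (floating-point reduction order varies across
BLAS implementations and thread counts).
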