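---
title: "Methods: phantom-based small-structure volumetry with hyposeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based small-structure volumetry with hyposeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Group-level atrophy studies of small brain structures — the motivating case
is the hypothalamus (~0.8 cm^3) in amyotrophic lateral sclerosis — need three
ingredients: a per-subject segmentation of the structure and of the
intracranial compartment (ICV) from T1-weighted MRI, a head-size
normalization of the structure volume, and statistics robust enough to
survive the occasional segmentation failure. `hyposeg` implements that whole
chain as a seeded, reproducible pipeline, and ships a synthetic phantom
generator with exact ground truth so that every stage can be exercised,
measured and tested without patient data.

## The phantom model

A phantom is an intensity field on a regular voxel grid (mm geometry
throughout, 0-based voxel indexing at the NIfTI interface):

* a bright ellipsoidal *intracranial compartment* (intensity `tissue`,
  default 0.6) on a dark background (0.1), with a 2:2:1 semi-axis anisotropy;
* a small bilateral *target structure* inside it: two mirrored half-ellipsoids
  flanking a midline gap (default 1 mm at desk scale), with a low contrast
  offset (+0.25) on top of the tissue level. The bilateral shape forces the
  segmenter to handle anterior/posterior edge slices where partial structures
  appear, the regime where real segmentations disagree most;
* a per-scan affine contrast transform (`gain`, `offset`), an optional simple
  multiplicative intensity gradient, and additive Gaussian noise
  (`noise_sd`, default 0.03).

Realized target masks are calibrated: the semi-axes are scaled by a binary
search on the voxelized count, so the discrete mask volume tracks the
requested volume far within the 5% discretization band at every grid scale.

Cohorts draw per-subject volumes log-normally (positivity guaranteed; only
means and SDs are specified for the real populations, so the family is a
modelling choice). Two points deserve emphasis:

* **ICV coupling.** Target volume scales proportionally with the subject's
  ICV (`icv_coupling = 1`) around the group mean. Normalizing to ICV only
  removes variance when structure size co-varies with head size — that is the
  reason head-size normalization exists. With uncoupled draws, normalization
  would *add* variance and misrepresent the design the pipeline emulates.
* **Atrophy effect.** Case subjects draw from a mean reduced by
  `effect_fraction` (default 0.10, matching the reported test-set reduction
  of about 10%).

Desk-scale defaults: 32 x 32 x 16 grids at 1 mm, control mean target volume
240 mm^3 (a scaled-down structure, ~240 voxels), ICV mean 3600 mm^3 with SD
325 — the same ICV coefficient of variation (~9%) as the reported
1532 +/- 139 cm^3 control ICVs. Full-scale geometry (512 x 512 x 50 at
0.125 x 0.125 x 0.5 mm) is available for the analysis-block format itself.

What the phantoms do **not** emulate: cortical anatomy and neighbouring grey
matter structures of similar intensity, scanner-specific bias fields beyond a
linear gradient, partial-volume mixtures at boundaries, motion artifacts, or
inter-site protocol variation. Passing tests on phantoms therefore validate
the *pipeline machinery* (geometry, losses, metrics, QC, statistics), not
clinical segmentation accuracy.

## Preprocessing

`align_to_axis()` performs a rigid rotation about the volume centre mapping
the anterior-posterior landmark axis onto the slice normal, so "coronal"
cutting planes are perpendicular to it. Intensities are interpolated
trilinearly, labels with nearest-neighbour — the standard choice that keeps
masks binary; the interpolation kernel of the emulated workflow is not
documented, so linear/nearest is a design decision. `resample_block()`
extracts the fixed analysis block (default 512^2 x 50 at 0.125/0.5 mm),
centred on the target centroid when ground truth exists, else on a supplied
landmark.

A caveat worth knowing: nearest-neighbour label resampling preserves physical
volume well (within 5% for structures of a few hundred voxels) only in the
genuine *upsampling* regime the pipeline uses (spacing ratios of roughly 5-8x
refinement). At resampling ratios near 1, phase aliasing of the voxelized
boundary can move small-structure volumes by 10% or more; the property tests
therefore probe the upsampling regime.

## Contrast augmentation

Training sets are expanded with per-copy contrast shifts: normalize to
[0, 1], apply `gain * x^gamma + offset`, clip, rescale. The transform family
and its default ranges (gain 0.5-1.5, offset +/-0.2, gamma 0.7-1.4; the
pipeline uses milder ranges matched to the generator's scan-to-scan
variability) are artifact choices — the emulated workflow names contrast
shifting without specifying the transform. Masks are never touched, and the
transform is monotone wherever no clipping occurs, preserving anatomical
structure. The default factor of 6 reflects the roughly 6-7x expansion of
the motivating study's training set; the pipeline default (2) favours
wall-clock time at desk scale.

## The segmenter

A native 2-D encoder-decoder with "U" topology: `depth` contracting stages
(two convolution rounds + 2x2 max pooling), a bottleneck, and a symmetric
expanding path (nearest-neighbour upsampling + convolution) with skip
connections at every resolution, ending in a per-pixel softmax over
background/target. The `encoder_family` tag sets the block style in both
paths:

| family          | block style                                   |
|-----------------|-----------------------------------------------|
| vgg-like        | plain double 3x3 convolutions                 |
| resnet-like     | double 3x3 with 1x1-projected identity sum    |
| inception-like  | parallel 3x3 / 1x1 branches, concatenated     |
| efficient-like  | depthwise-separable convolutions (fewest parameters) |

These are reduced-width emulations of the backbone *styles*, not
layer-for-layer replicas; `efficient-like` (the default, mirroring the best
backbone of the motivating study) has the lowest parameter count, which the
tests assert. No pretrained weights are used: at desk scale the networks
train from seeded He initialization in minutes, and transfer learning is out
of scope.

Since no deep-learning framework is available to R in this package's
dependency set, the layers, backpropagation and the Adam optimizer are
implemented natively: 3x3 convolutions as im2col gathers followed by BLAS
GEMM, backward-data passes as forward convolutions with 180-degree-flipped,
channel-transposed kernels (exact for zero-padded stride-1 convolution). The
analytic gradients are verified against central finite differences in the
test suite for every block family.

**Loss.** Categorical cross-entropy (mean per pixel) plus `1 -` soft Jaccard
of the foreground class, pooled over the batch. Whether the Jaccard term
should be per-image or per-batch, foreground-only or all-class, is not
documented in the emulated protocol; foreground-per-batch is the package's
default and the loss is exposed as `combined_loss()` with both terms
reported.

**Protocol.** Adam (step size 0.001, moment decays 0.9/0.999), batch size 4,
up to 25 epochs with early stopping after 10 epochs without validation-loss
improvement, restoring the weights of the best-validation epoch — all exposed
in `train_config()`. Validation IoU is monitored per epoch. The pipeline adds
an optional *quality-based* stop (`iou_target`, default 0.95 in
`run_config()`): training ends as soon as validation IoU reaches the target.
This equalizes convergence *quality* across seeds rather than epoch count;
under-converged segmenters show a size-dependent boundary bias (small
structures dilated toward the training-set mean) that systematically
compresses group differences in the volumetry.

Random initialization occasionally lands in a dead basin (no foreground
learned at all; observed once at 64-pixel input, with validation IoU pinned
at zero). `train_unet()` guards against this deterministically: if the
validation IoU stays below 0.05 for the first three epochs, weights are
reinitialized from a seed derived from the original one and training
restarts (at most twice).

The pipeline trains the target-structure model on the slice block containing
the structure (+/- 2 slices) — the desk-scale analogue of the pre-selected
coronal block — and a second model of the same architecture for the ICV task,
which is high-contrast and converges in two epochs without augmentation.

## Evaluation metrics

Per volume: confusion counts (TP/FP/TN/FN), IoU, precision, recall, Dice
(with `dice = 2 iou / (1 + iou)` holding identically), and the 95%
Hausdorff distance. HD95 extracts boundary voxels (foreground with a
face-connected background neighbour; array edges count as boundary), computes
both directed nearest-neighbour distance sets in mm honouring anisotropic
spacing, takes an upper percentile of each directed set and returns the
maximum. The percentile uses the interpolated rule `h = min(n, 0.95 n + 1)`
on order statistics: it interpolates linearly for large boundary sets, equals
the maximum for sets of up to 20 points, and can never exceed the exact
Hausdorff distance. Whether the original analysis pooled directed sets or
took the maximum of directed percentiles is undocumented; the choice here is
recorded and oracle-tested. Undefined cases (empty masks) are reported as
`NA`, never coerced to 0.

Method agreement uses Bland-Altman analysis with the approximate t-based
confidence intervals: bias CI `d +/- t(0.975, n-1) SD/sqrt(n)`, limits of
agreement `d +/- 1.96 SD` with CI half-width `t sqrt(3 SD^2 / n)`.

## Volumetry, normalization and QC

Volumes are foreground voxel counts times voxel volume (bilateral components
summed). Head-size normalization rescales by the control-mean ICV:
`v_norm = v_target / v_icv * mean(v_icv | control, accepted)` — the identity
when the subject's ICV equals the reference, and invariant under joint
scaling of both volumes.

Quality control applies Tukey fences (`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`,
type-7 quartiles) per group in a fixed cascade: empty segmentation, then ICV
outliers, then raw target-volume outliers, then normalized-volume outliers;
each subject keeps the first triggered reason. The emulated study reports
mixed rejection reasons without an explicit precedence, so the cascade order
is a documented design decision. All fences are frozen on the first pass
(no iterative re-fencing) and returned with the records, making QC
idempotent on the accepted subset. Acceptance rates are reported pooled and
per group.

## Group statistics

Agreement between predicted and true volumes uses a Shapiro-Wilk-gated
paired test (paired t when the differences look normal at alpha = 0.05,
Wilcoxon signed-rank otherwise; zero-variance differences produce a
degenerate report rather than a fabricated p-value). The case-control
comparison of normalized volumes uses a two-sided pooled-variance Student
t-test — "unpaired t-test" leaves Welch vs pooled open; pooled is the
package's logged choice. Percent difference is
`(mean_control - mean_case) / mean_control * 100` with the control mean as
denominator (the convention consistent with all reported reductions),
emitted to one decimal and as a rounded integer.

## Reproducibility and numerical choices

* One global seed fans out deterministically to every stage
  (`derive_seed()`); phantom generation, augmentation sampling, weight
  initialization and shuffling are all bit-reproducible per seed.
* Max-pooling ties break to the first window element in a fixed order;
  argmax ties at softmax 0.5 classify as foreground.
* Near-integer interpolation coordinates are snapped at 1e-9 so
  identity-spacing resampling is an exact crop.
* Cross-entropy uses an epsilon of 1e-7 inside the logarithm.
* Provenance (config hash, stage seeds, package and R versions) is written
  to every run directory.

## Problem sizes in the shipped tests

The test suite exercises the full pipeline at desk scale: study cohorts of
60 + 60 subjects on 32^2 x 16 grids with 10 labelled training subjects
(effect recovery across five seeds), a 40-training-volume run on 64^2 slices
for held-out segmentation quality, and oracle cross-checks of every metric on
hundreds of random small masks. These sizes were chosen so the entire suite
runs on a single CPU in well under half an hour while keeping every
statistical check adequately powered.

## Known limitations

* Phantom realism is deliberately minimal (see above); Dice values on
  phantoms are optimistic relative to clinical data.
* The segmenter is 2-D slice-wise by design; no 3-D context is used.
* NN label resampling is volume-safe only for genuine upsampling.
* The normalized-volume QC stage can flag legitimate extreme anatomies;
  fences are per group but not age- or sex-adjusted.
* Training wall-clock grows quickly with plane size (im2col in base R);
  the intended scale is the desk-scale study of the vignette, not 512^2
  clinical volumes.
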