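---
title: "Methods: the 2.5-D slice-submodule model and its companion analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 2.5-D slice-submodule model and its companion analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the
design decisions taken where the method's description left room.

## The model

A template-space FDG PET volume with `nx × ny × nz` voxels is treated
as three stacks of 2-D planes: `nx` sagittal, `ny` coronal, `nz` axial
(1-based indices throughout the package; millimetre coordinates exist
only through the NIfTI affine). For an MNI-shaped grid this gives
`91 + 109 + 91 = 291` planes. Each plane has its own submodule — no
weights are shared — consisting of four stages of

> convolution (3×3 kernel, stride 1, zero "same" padding) →
> batch normalization → ReLU → max pooling (2×2, stride 2)

with 32, 64, 128 and 128 filters, followed by flattening and a single
fully connected unit with sigmoid activation. The 291 per-slice
probabilities are concatenated and fused by one more fully connected
sigmoid unit into the final probability of amyloid positivity; a
subject is classified positive only when this probability strictly
exceeds 0.5. Convolution weights are He-initialized, the fully
connected units Xavier-initialized. Training minimizes binary
cross-entropy on the final output end to end with Adam (learning rate
1e-4), mini-batches of 4, for at most 30 epochs; after every epoch the
loss on a stratified 20% internal-validation split is recorded and the
weights of the epoch with the lowest validation loss are the ones
returned. Inference runs batch normalization on its running moments
and is deterministic.

Resolution is only ever reduced by pooling (floor division for odd
sizes: 91 → 45 → 22 → 11 → 5), so four stages require every in-plane
dimension to be at least 16; the constructors enforce this and refuse
smaller grids by name. The per-slice feature length after pooling is
what makes submodules of different plane shapes differ — the
convolutional stack is shape-agnostic, so parameter counts differ only
in the final fully connected layer.

Three points were genuinely open and are fixed here as package
conventions:

- **Padding** is "same" (zero padding of 1), the common reading that
  keeps a 4-deep stack valid for 91-pixel planes.
- **Loss** is a single binary cross-entropy on the fused output; the
  per-slice sigmoids receive no auxiliary supervision, and the head
  consumes the *post*-sigmoid submodule values.
- **Conv biases** are retained for architectural fidelity although
  batch normalization makes their gradient exactly zero (the mean
  subtraction absorbs any bias); this is verified by a
  finite-difference test.

Non-finite training loss aborts with a diagnostic rather than
continuing. Training on a single-class sample is refused.

### Desk-scale configuration

The published-scale configuration (291 submodules, 32/64/128/128
filters) is faithful but deliberately heavy. For the package's own
experiments and tests a scaled-down configuration is used: 24 × 28 ×
24 grids (76 submodules), 8/16/32/32 filters, learning rate 1e-3, 6
epochs. The learning rate departs from the reference recipe because at
~40 mini-batches per epoch a 1e-4 step makes 6-epoch training
hopelessly undertrained; 1e-3 is the conventional small-model Adam
default and was fixed before any evaluation was run. Everything else
(optimizer, batch size, checkpoint rule, threshold) is unchanged.

## Preprocessing

The only intensity preprocessing is reference-region normalization:
every voxel is divided by the mean intensity over the pons mask taken
from the atlas. This removes the subject-level global uptake scale
(dose, weight, scanner gain) while leaving regional contrasts intact;
it is idempotent and invariant to positive rescaling, and the package
asserts both. No per-slice standardization and no brain masking is
applied before the model — out-of-brain voxels enter as zeros, and the
corresponding boundary submodules simply learn from (and contribute)
nothing informative. Spatial registration is assumed done upstream:
inputs are template-space volumes.

## SUVR labelling

Ground-truth amyloid status is defined from amyloid-tracer volumes by
regional SUVR: the mean over a target region divided by the mean over
the cerebellum (chosen as reference for its low amyloid deposition).
Three rules are built in: florbetapir (global composite SUVR > 1.11,
computed as the voxel mean over the union of the target regions),
PiB (> 1.4 in at least one of the four target regions) and
florbetaben (> 1.478, same any-of form). Comparisons are strict:
equality at the threshold is negative. The four-region set (frontal,
cingulate/precuneus, lateral temporal, lateral parietal in the
clinical setting) is configuration, not code — any atlas region names
can be supplied, and the toy-atlas tests use arbitrary regions.
Whether "cerebellar uptake" means whole cerebellum or grey matter only
is left to the caller through the explicit reference-region name.

## Interpretation: slice significance and Cartesian points

Class-activation maps need spatial feature maps at the fusion point;
here every plane is collapsed to a scalar before fusion, so CAM cannot
apply. Instead the submodule predictions themselves are analyzed:

1. Subjects are grouped by the **model's** classification (not the
   ground truth — the aim is to explain the model's decision).
2. Each submodule's probabilities are compared between groups with a
   two-tailed two-sample t test at alpha = 0.05. Welch's test is the
   default for robustness; a pooled-variance option exists for exact
   replication attempts. Constant outputs in both groups are excluded
   rather than called significant. No multiple-testing correction is
   applied across the submodules, matching the reference procedure.
3. The significant sagittal, coronal and axial indices are intersected:
   point (x, y, z) is plotted when all three of its planes are
   significant. The point count is therefore the product of the three
   set sizes — 2 × 2 × 2 = 8, or 20 × 27 × 24 = 12,960.
4. Because this product construction over-plots by design (the method
   itself acknowledges many unrelated points), only atlas regions
   collecting strictly more than `min_points` points (default 50, the
   same value as the voxel-wise cluster threshold) are reported.

"Clusters with more than 50 points from the atlas" is read as
per-region point counts, matching how surviving regions are reported;
connected components of the point cloud would be an alternative
reading, and the point matrix is exposed so users can apply their own
grouping. `min_points` is configurable because toy volumes have far
fewer slices than MNI grids.

There is no gold standard for which regions the model "really" uses,
so recovery is validated only on synthetic cohorts with seeded
discriminative regions.

## Voxel-wise analysis

The comparison surface is a classical mass-univariate two-sample t
map between amyloid-positive and negative subjects over a brain mask,
with positive t meaning higher metabolism in positives. The pooled
variance test is the default here (the classical two-sample imaging
design); the asymmetry with the interpretation module's Welch default
is deliberate — submodule probability distributions are often strongly
heteroscedastic between predicted classes, voxel intensities much less
so. Zero-variance voxels are dropped from the mask with a count kept.

Thresholding offers uncorrected p (e.g. < 0.001), Bonferroni, and
permutation max-T familywise correction. Random-field-theory FWE as
implemented in SPM is **not** reproduced — it needs smoothness
estimation out of scope here; permutation is exact at desk scale and
is the recommended corrected mode. Suprathreshold voxels are grouped
into connected components separately per t sign (18-connectivity by
default, the common imaging convention; 6 and 26 available) and
components survive only with size strictly greater than k (default 50
voxels).

## Evaluation

Metrics are the standard confusion-matrix set plus rank-based AUC with
the midrank tie convention (equal to all-pairs concordance with ties
counting one half). F1 uses the form `2TP / (2TP + FP + FN)`, which
equals the harmonic mean of precision and sensitivity whenever both
are defined. The repeated protocol draws a fresh stratified 80/20
split per repetition (50 in the reference protocol), trains, evaluates
internally and optionally on a fixed external set, and summarizes each
metric as mean with a 95% CI. The CI method was unstated in the
reference presentation; the default is the normal approximation
`mean ± 1.96·SD/√R` across repetitions, with a percentile bootstrap
option, and both are labelled as across-repetition intervals. The
"best model" is the repetition with the highest internal-validation
AUC, reported with its external metrics. Subgroup reports (CU / MCI /
dementia) simply restrict the metric computation; a subgroup missing a
class reports the metrics that remain defined and NA elsewhere.

## Synthetic cohorts

The generator emulates the statistical structure the analyses assume,
not PET physics. A toy atlas places an ellipsoidal brain on the grid,
splits its inferior cap into pons and cerebellum reference regions and
tessellates the rest into contiguous cortical parcels (every region
≥ 60 voxels, enforced). Each subject's volume is

> global scale × per-region baseline, effect factor for positives,
> additive Gaussian voxel noise, optional separable Gaussian smoothing

where baselines are drawn once per cohort from 0.8–1.2, the global
scale is lognormal (sdlog 0.1) — exactly the nuisance pons
normalization removes — positives have `hypo_regions` multiplied by
(1 − effect) and `hyper_regions` by (1 + effect), and FWHM→sigma uses
the standard `2√(2 ln 2)` conversion with edge renormalization.
Prevalence is exact-count by default (reproducible class balance in
small cohorts; a binomial mode exists), and diagnosis subgroups are
assigned independently of amyloid label, mirroring how real cohorts
mix diagnoses within each amyloid class. The amyloid-tracer generator
paints target-region SUVR levels above threshold + margin for
positives and below threshold − margin for negatives, so rule recovery
is exact for nonzero margins and a coin flip at the boundary.

What this does **not** emulate: scanner point-spread, attenuation or
reconstruction artefacts, anatomical variability, partial-volume
effects, registration error, or realistic effect topographies.
Passing the parameter-recovery tests therefore demonstrates that the
implementation recovers what it was built to recover under its own
assumptions — it says nothing about clinical accuracy on real data,
whose headline numbers require the access-restricted cohorts.

Default study conditions for the recovery experiments, chosen once as
field-plausible magnitudes (the reference work does not quantify its
group effect sizes): 15% regional effect, 5% voxel noise, 200
subjects at 50% prevalence on a 24 × 28 × 24 grid. At these settings
the scaled network separates the classes essentially perfectly, and
both the interpretation stage and the voxel-wise clusters land on the
seeded regions.

## Numerical conventions

- Batch-norm epsilon 1e-5, momentum 0.1, biased variance for
  normalization, unbiased for the running estimate.
- BCE probabilities clamped to [1e-7, 1 − 1e-7].
- Pooling argmax ties resolve to the earliest position in column-major
  order (deterministic).
- All indices 1-based; voxel-to-mm only via the affine.
- Fixed seeds make cohort generation bit-identical and training
  reproducible on a single machine; exact bit-reproducibility across
  BLAS builds is not promised.

## Known limitations

- The full 291-submodule, 32/64/128/128 configuration is supported
  but slow in this implementation; the package is built for
  desk-scale scientific validation, not GPU-scale training.
- Random-field-theory FWE is not implemented (see above).
- No covariate adjustment (age/sex GLM) in the voxel-wise stage.
- Model calibration (reliability of the predicted probabilities) is
  not assessed.
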