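# slicenet

Amyloid PET positivity from FDG PET volumes with a 2.5-D
slice-submodule convolutional network.

## The problem

Amyloid PET directly measures cerebral beta-amyloid — the defining
pathology of the Alzheimer's continuum — but it is expensive and not
widely available. FDG PET, which images regional glucose metabolism, is
routine in memory clinics, and amyloid-positive patients show a
characteristic metabolic signature: temporoparietal/default-mode
hypometabolism with relative preservation (even relative increase) of
sensorimotor cortex. `slicenet` implements a deep-learning pipeline
that exploits this signature to classify amyloid status from an FDG
volume alone, together with the quantification, interpretation and
statistical machinery around it:

- **2.5-D model.** A template-space volume of `nx × ny × nz` voxels is
  decomposed into all of its sagittal, coronal and axial planes
  (`91 + 109 + 91 = 291` for an MNI-shaped volume). Each plane feeds
  its own independent 2-D CNN submodule — four stages of
  `conv 3×3 (stride 1, same padding) → batch norm → ReLU → max pool
  2×2 (stride 2)` with 32/64/128/128 filters, ending in a fully
  connected sigmoid unit — and one final fully connected sigmoid head
  fuses the 291 per-slice predictions into a single probability
  P(amyloid-positive). Training uses binary cross-entropy, Adam
  (learning rate 1e-4), mini-batches of 4, at most 30 epochs, and
  keeps the weights of the epoch with the lowest internal-validation
  loss. A subject is called positive when the final probability is
  strictly greater than 0.5.
- **Ground-truth labelling.** Regional SUVRs (region mean over
  cerebellar mean) with the three tracer rules: florbetapir — global
  composite SUVR > 1.11; PiB — SUVR > 1.4 in at least one of four
  target regions; florbetaben — the same any-of rule at 1.478. All
  thresholds strict.
- **Interpretation.** Class-activation mapping does not apply to this
  architecture (each submodule collapses its plane to a scalar before
  fusion), so the model is interrogated through its submodules: a
  two-sample t test per slice between the subjects the model
  classified positive and negative, the Cartesian product of the
  significant sagittal × coronal × axial slice indices plotted as a
  3-D point cloud, and the atlas regions collecting strictly more than
  50 points reported as the model's basis.
- **Voxel-wise comparison surface.** Classical two-sample t maps
  between amyloid groups with uncorrected p < 0.001 (or Bonferroni /
  permutation max-T familywise correction) and cluster-extent
  threshold k > 50 voxels.
- **Synthetic cohorts.** A generator that emulates the study structure
  (two classes at configurable prevalence, regional hypo-/
  hypermetabolism, global-scale nuisance, voxel noise, smoothing) plus
  a toy atlas with pons and cerebellum reference regions, so the whole
  pipeline is testable without access-restricted clinical data.

## Worked example

```r
library(slicenet)

atlas <- generate_toy_atlas(c(16, 16, 16), n_cortical_regions = 4, seed = 2)
cfg <- cohort_config(c(16, 16, 16), n_subjects = 20, prevalence = 0.5,
                     hypo_regions = 1, hyper_regions = 2,
                     effect_size = 0.30, noise_sd = 0.03, seed = 31)
cohort <- generate_cohort(cfg, atlas)
cohort
#> pet_cohort: 20 subjects, dims 16 x 16 x 16, 10 positive / 10 negative

volumes <- lapply(cohort$volumes, normalize_by_reference, atlas = atlas)
net_cfg <- slicenet_config(c(16, 16, 16), conv_filters = c(4, 8, 8, 8),
                           learning_rate = 1e-3, max_epochs = 5, seed = 7)
fit <- slicenet(volumes, cohort$meta$label, net_cfg)
fit
#> slicenet 2.5-D model
#>   volume dims: 16 x 16 x 16
#>   submodules:  48 (16 + 16 + 16)
#>   filters:     4/8/8/8
#>   trained:     5 epochs, checkpoint at epoch 5 (val loss 0.4433)

preds <- predict(fit, volumes, subject_ids = cohort$meta$subject_id)
auc_score(preds$probability[fit$val_idx], cohort$meta$label[fit$val_idx])
#> [1] 1
```

The fitted model holds one submodule per slice; `preds` carries the
final probability and predicted class per subject plus the full
48-element submodule probability vector each prediction is fused from.
Interpretation intersects the per-axis significant slices into a point
cloud and tallies it per atlas region:

```r
interp <- interpret_slicenet(preds, atlas, alpha = 0.05, min_points = 5)
interp
#> slicenet_significance (alpha = 0.05)
#>   significant slices: 14 sagittal, 13 coronal, 11 axial
#>   Cartesian points:   2002
#>   surviving ROIs (> 5 points): cortical_02, cortical_01, cortical_04, cortical_03
```

(2002 = 14 × 13 × 11: the point count is always the product of the
per-axis set sizes.) The voxel-wise surface tells the same story with
conventional mapping statistics — one positive cluster where the
positives' metabolism was raised, one negative cluster where it was
seeded to drop:

```r
stat <- voxelwise_ttest(volumes, cohort$meta$label, mask = atlas$labels > 0)
threshold_and_cluster(stat, p_threshold = 0.001, k = 10)
#> cluster_result: p < 0.001 (none), k > 10, 18-connectivity
#>   id sign size    peak_t peak_x peak_y peak_z
#> 1  1    1  367  36.31906     12      9     12
#> 2  2   -1  355 -38.48350      6      6     11
```

SUVR labelling follows the tracer rules with strict thresholds:

```r
s <- compute_roi_suvr(cohort$volumes[[1]], atlas,
                      roi_names = c("cortical_01", "cortical_02"))
classify_positivity(s, positivity_rule("pib"))
```

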