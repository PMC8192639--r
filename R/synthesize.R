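#' Configuration for a synthetic PET cohort
#'
#' Describes a two-class cohort of template-space volumes with
#' class-dependent regional intensity changes: amyloid-positive subjects
#' get a fractional intensity DECREASE ("hypometabolism") in
#' `hypo_regions` and an INCREASE in `hyper_regions`, echoing the
#' temporoparietal/default-mode hypometabolism and sensorimotor relative
#' preservation seen in amyloid-positive FDG PET. Baseline structure is a
#' per-region constant (drawn once from `baseline_range`) times a
#' per-subject lognormal global scale; the global scale is the nuisance
#' that reference-region normalization removes.
#'
#' @param dims Voxel counts `(nx, ny, nz)`.
#' @param n_subjects Number of subjects.
#' @param prevalence Fraction of amyloid-positive subjects in `[0, 1]`.
#' @param hypo_regions,hyper_regions Disjoint vectors of atlas region names
#'   or ids carrying the class-dependent decrease / increase.
#' @param effect_size Fractional intensity change (0.10 = 10\%), `>= 0`.
#' @param noise_sd Voxel noise SD relative to the subject's global scale.
#' @param smooth_fwhm_vox Gaussian smoothing FWHM in voxels (0 = none).
#' @param prevalence_mode `"exact"` (default; exactly
#'   `round(prevalence * n)` positives, reproducible class balance) or
#'   `"binomial"`.
#' @param subgroup_props Named proportions for the `CU`/`MCI`/`dementia`
#'   diagnosis tags, assigned independently of amyloid label.
#' @param baseline_range Range of the per-region baseline constants.
#' @param global_scale_sdlog `sdlog` of the per-subject lognormal scale.
#' @param seed RNG seed; a fixed seed gives a bit-identical cohort.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(dims, n_subjects, prevalence = 0.5,
                          hypo_regions = integer(0),
                          hyper_regions = integer(0),
                          effect_size = 0.10, noise_sd = 0.05,
                          smooth_fwhm_vox = 0,
                          prevalence_mode = c("exact", "binomial"),
                          subgroup_props = c(CU = 0.35, MCI = 0.45,
                                             dementia = 0.20),
                          baseline_range = c(0.8, 1.2),
                          global_scale_sdlog = 0.1,
                          seed = 1L) {
  prevalence_mode <- match.arg(prevalence_mode)
  stopifnot(length(dims) == 3, n_subjects >= 1)
  if (prevalence < 0 || prevalence > 1)
    stop("prevalence must be in [0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (length(intersect(hypo_regions, hyper_regions)) > 0)
    stop("hypo_regions and hyper_regions must be disjoint")
  structure(list(
    dims = as.integer(dims), n_subjects = as.integer(n_subjects),
    prevalence = prevalence, hypo_regions = hypo_regions,
    hyper_regions = hyper_regions, effect_size = effect_size,
    noise_sd = noise_sd, smooth_fwhm_vox = smooth_fwhm_vox,
    prevalence_mode = prevalence_mode, subgroup_props = subgroup_props,
    baseline_range = baseline_range,
    global_scale_sdlog = global_scale_sdlog, seed = as.integer(seed)
  ), class = "cohort_config")
}

draw_labels <- function(config) {
  n <- config$n_subjects
  if (config$prevalence_mode == "exact") {
    npos <- round(config$prevalence * n)
    if (npos < 1 || npos > n - 1)
      stop("exact-count prevalence ", config$prevalence, " with n = ", n,
           " leaves a class empty")
    sample(c(rep(1L, npos), rep(0L, n - npos)))
  } else {
    rbinom(n, 1L, config$prevalence)
  }
}

draw_subgroups <- function(config) {
  sample(names(config$subgroup_props), config$n_subjects, replace = TRUE,
         prob = config$subgroup_props)
}

#' Generate a synthetic FDG-like cohort
#'
#' Each volume is `global_scale * region_baseline`, with the positive
#' class's `hypo_regions` multiplied by `1 - effect_size` and
#' `hyper_regions` by `1 + effect_size`, plus Gaussian voxel noise inside
#' the brain and optional separable Gaussian smoothing. Reference regions
#' (pons, cerebellum) carry the global scale but no class effect, so
#' dividing by the pons mean removes the nuisance scale without touching
#' the group difference.
#'
#' @param config A [cohort_config()].
#' @param atlas A `pet_atlas` whose region ids cover the configured
#'   effect regions.
#' @return A `pet_cohort`: list with `volumes` (list of 3-D arrays),
#'   `meta` (data frame `subject_id`, `label`, `subgroup`), `atlas`,
#'   `config`.
#' @examples
#' atl <- generate_toy_atlas(c(16, 16, 16), 4)
#' coh <- generate_cohort(cohort_config(c(16, 16, 16), 10,
#'   hypo_regions = 1, hyper_regions = 2, seed = 7), atl)
#' table(coh$meta$label)
#' @export
generate_cohort <- function(config, atlas) {
  stopifnot(inherits(config, "cohort_config"), inherits(atlas, "pet_atlas"))
  if (!all(dim(atlas$labels) == config$dims))
    stop("config dims and atlas dims differ")
  hypo_ids <- atlas_region_id(atlas, config$hypo_regions)
  hyper_ids <- atlas_region_id(atlas, config$hyper_regions)

  set.seed(config$seed)
  labels <- draw_labels(config)
  subgroups <- draw_subgroups(config)

  baseline <- runif(nrow(atlas$regions), config$baseline_range[1],
                    config$baseline_range[2])
  base <- array(0, config$dims)
  for (r in seq_len(nrow(atlas$regions)))
    base[atlas$labels == atlas$regions$id[r]] <- baseline[r]

  eff <- array(1, config$dims)
  if (length(hypo_ids))
    eff[atlas$labels %in% hypo_ids] <- 1 - config$effect_size
  if (length(hyper_ids))
    eff[atlas$labels %in% hyper_ids] <- 1 + config$effect_size

  brain <- atlas$labels > 0L
  nb <- sum(brain)
  volumes <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    g <- rlnorm(1, 0, config$global_scale_sdlog)
    v <- g * base
    if (labels[i] == 1L) v <- v * eff
    v[brain] <- v[brain] + rnorm(nb, 0, config$noise_sd * g)
    if (config$smooth_fwhm_vox > 0)
      v <- gaussian_smooth_3d(v, config$smooth_fwhm_vox)
    volumes[[i]] <- v
  }

  structure(list(
    volumes = volumes,
    meta = data.frame(subject_id = sprintf("S%04d", seq_len(config$n_subjects)),
                      label = labels, subgroup = subgroups,
                      stringsAsFactors = FALSE),
    atlas = atlas, config = config
  ), class = "pet_cohort")
}

#' Generate a synthetic amyloid-tracer cohort
#'
#' Produces volumes for exercising the SUVR positivity rules: the
#' cerebellum baseline is fixed at 1 (times the subject's global scale) and
#' each of the `target_rois` is painted at a level whose ratio to the
#' cerebellum lies above `threshold + margin` for positives and below
#' `threshold - margin` for negatives. With a nonzero margin the
#' rule-based classifier recovers the generating labels exactly; with
#' `margin = 0` subjects sit at the decision boundary and voxel noise makes
#' recovery there a coin flip.
#'
#' @inheritParams generate_cohort
#' @param target_rois Names (or ids) of the four target regions; defaults
#'   to the first four cortical regions of the atlas.
#' @param threshold SUVR positivity cutoff the cohort is built around.
#' @param margin Half-gap between the classes' SUVR levels.
#' @param spread Width of the uniform SUVR draw beyond the margin.
#' @return A `pet_cohort`; `meta` additionally records the generating SUVR
#'   levels' side of the threshold as `label`.
#' @export
generate_amyloid_cohort <- function(config, atlas,
                                    target_rois = NULL,
                                    threshold = 1.4, margin = 0.2,
                                    spread = 0.3) {
  stopifnot(inherits(config, "cohort_config"), inherits(atlas, "pet_atlas"))
  if (!all(dim(atlas$labels) == config$dims))
    stop("config dims and atlas dims differ")
  if (is.null(target_rois)) {
    cort <- atlas$regions$name[!atlas$regions$is_reference]
    if (length(cort) < 4) stop("atlas has fewer than 4 cortical regions")
    target_rois <- cort[1:4]
  }
  target_ids <- atlas_region_id(atlas, target_rois)
  cereb_id <- atlas_region_id(atlas, "cerebellum")

  set.seed(config$seed)
  labels <- draw_labels(config)
  subgroups <- draw_subgroups(config)

  baseline <- runif(nrow(atlas$regions), config$baseline_range[1],
                    config$baseline_range[2])
  baseline[atlas$regions$id == cereb_id] <- 1
  base <- array(0, config$dims)
  for (r in seq_len(nrow(atlas$regions)))
    base[atlas$labels == atlas$regions$id[r]] <- baseline[r]

  brain <- atlas$labels > 0L
  nb <- sum(brain)
  roi_masks <- lapply(target_ids, function(id) atlas$labels == id)
  volumes <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    g <- rlnorm(1, 0, config$global_scale_sdlog)
    v <- g * base
    for (m in roi_masks) {
      level <- if (labels[i] == 1L)
        threshold + margin + runif(1, 0, spread)
      else
        max(0.05, threshold - margin - runif(1, 0, spread))
      v[m] <- g * level
    }
    v[brain] <- v[brain] + rnorm(nb, 0, config$noise_sd * g)
    if (config$smooth_fwhm_vox > 0)
      v <- gaussian_smooth_3d(v, config$smooth_fwhm_vox)
    volumes[[i]] <- v
  }

  structure(list(
    volumes = volumes,
    meta = data.frame(subject_id = sprintf("S%04d", seq_len(config$n_subjects)),
                      label = labels, subgroup = subgroups,
                      stringsAsFactors = FALSE),
    atlas = atlas, config = config, target_rois = target_rois
  ), class = "pet_cohort")
}

#' @export
print.pet_cohort <- function(x, ...) {
  cat("pet_cohort: ", length(x$volumes), " subjects, dims ",
      paste(dim(x$volumes[[1]]), collapse = " x "), ", ",
      sum(x$meta$label == 1L), " positive / ",
      sum(x$meta$label == 0L), " negative\n", sep = "")
  invisible(x)
}
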