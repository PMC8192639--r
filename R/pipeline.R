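#' Run the full analysis pipeline
#'
#' Chains the package's stages — simulate (or load) a cohort, normalize
#' by the pons, train the 2.5-D network, predict, evaluate on the
#' internal validation subjects, interpret the submodule predictions,
#' and compute the voxel-wise t map with cluster thresholding — and
#' writes every stage's outputs plus a manifest recording the
#' configuration, the seed and an MD5 checksum of each output file.
#' Identical configuration and seed reproduce identical output
#' checksums.
#'
#' @param config A named list, or the path of a JSON file holding one.
#'   Recognized entries (all stage blocks optional):
#'   \describe{
#'     \item{seed}{integer, used for every stage.}
#'     \item{paths}{`data` (existing cohort directory), `atlas`
#'       (existing atlas stem), `output` (output directory, required).}
#'     \item{simulate}{arguments of [cohort_config()] plus
#'       `n_cortical_regions`; used when no `paths$data` is given.}
#'     \item{model}{`conv_filters`, `learning_rate`, `batch_size`,
#'       `max_epochs`, `decision_threshold`, `val_fraction`.}
#'     \item{interpret}{`alpha`, `min_points`.}
#'     \item{voxelwise}{`p_threshold`, `correction`, `k`,
#'       `connectivity`.}
#'   }
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  paths <- config$paths %||% list()
  out_dir <- paths$output
  if (is.null(out_dir)) stop("config$paths$output is required")

  # fail fast on referenced inputs before writing anything
  if (!is.null(paths$data) && !dir.exists(paths$data))
    stop("data directory not found: ", paths$data)
  if (!is.null(paths$atlas) && !file.exists(paste0(paths$atlas, ".nii.gz")))
    stop("atlas not found at stem: ", paths$atlas)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage: cohort -------------------------------------------------
  if (!is.null(paths$data)) {
    cohort <- read_cohort(paths$data)
  } else {
    sim <- config$simulate %||% list()
    atlas <- if (!is.null(paths$atlas)) read_atlas(paths$atlas) else
      generate_toy_atlas(sim$dims %||% c(24, 28, 24),
                         sim$n_cortical_regions %||% 6L, seed = seed)
    cc <- cohort_config(
      dims = dim(atlas$labels),
      n_subjects = sim$n_subjects %||% 60L,
      prevalence = sim$prevalence %||% 0.5,
      hypo_regions = sim$hypo_regions %||% 1L,
      hyper_regions = sim$hyper_regions %||% 2L,
      effect_size = sim$effect_size %||% 0.15,
      noise_sd = sim$noise_sd %||% 0.05,
      smooth_fwhm_vox = sim$smooth_fwhm_vox %||% 0,
      seed = seed)
    cohort <- generate_cohort(cc, atlas)
  }
  labels <- cohort$meta$label

  # ---- stage: preprocessing -----------------------------------------
  norm_volumes <- lapply(cohort$volumes, normalize_by_reference,
                         atlas = cohort$atlas)

  # ---- stage: model --------------------------------------------------
  mcfg <- config$model %||% list()
  scfg <- slicenet_config(
    dims = dim(cohort$volumes[[1]]),
    conv_filters = mcfg$conv_filters %||% c(8L, 16L, 32L, 32L),
    learning_rate = mcfg$learning_rate %||% 1e-3,
    batch_size = mcfg$batch_size %||% 4L,
    max_epochs = mcfg$max_epochs %||% 6L,
    decision_threshold = mcfg$decision_threshold %||% 0.5,
    val_fraction = mcfg$val_fraction %||% 0.2,
    seed = seed)
  fit <- slicenet(norm_volumes, labels, scfg,
                  subject_ids = cohort$meta$subject_id)
  write.csv(fit$history, file.path(out_dir, "history.csv"),
            row.names = FALSE)

  # ---- stage: predictions & evaluation -------------------------------
  preds <- predict(fit, norm_volumes,
                   subject_ids = cohort$meta$subject_id)
  write.csv(as.data.frame(preds), file.path(out_dir, "predictions.csv"),
            row.names = FALSE)
  val_sel <- fit$val_idx
  metrics <- suppressWarnings(compute_metrics(
    labels[val_sel], probabilities = preds$probability[val_sel],
    threshold = scfg$decision_threshold))
  sub_rep <- subgroup_report(labels, preds$class, preds$probability,
                             cohort$meta$subgroup)
  jsonlite::write_json(
    list(validation = metrics[c("auc", "accuracy", "sensitivity",
                                "specificity", "f1", "n")],
         subgroups = sub_rep),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    na = "null")

  # ---- stage: interpretation -----------------------------------------
  icfg <- config$interpret %||% list()
  interp <- tryCatch(
    interpret_slicenet(preds, cohort$atlas,
                       alpha = icfg$alpha %||% 0.05,
                       min_points = icfg$min_points %||% 50L),
    error = function(e) e)
  if (inherits(interp, "error")) {
    jsonlite::write_json(list(error = conditionMessage(interp)),
                         file.path(out_dir, "interpretation.json"),
                         auto_unbox = TRUE)
  } else {
    jsonlite::write_json(
      list(alpha = interp$alpha,
           sig_x = interp$sig_x, sig_y = interp$sig_y,
           sig_z = interp$sig_z, n_points = nrow(interp$points),
           roi_counts = interp$roi_counts,
           surviving_rois = interp$surviving_rois),
      file.path(out_dir, "interpretation.json"), auto_unbox = TRUE,
      digits = NA)
  }

  # ---- stage: voxel-wise ----------------------------------------------
  vcfg <- config$voxelwise %||% list()
  sm <- voxelwise_ttest(norm_volumes, labels,
                        mask = cohort$atlas$labels > 0L)
  cl <- threshold_and_cluster(sm,
                              p_threshold = vcfg$p_threshold %||% 0.001,
                              correction = vcfg$correction %||% "none",
                              k = vcfg$k %||% 50L,
                              connectivity = vcfg$connectivity %||% 18L)
  write.csv(cl$clusters, file.path(out_dir, "clusters.csv"),
            row.names = FALSE)
  write_volume(sm$t_map, file.path(out_dir, "tmap.nii.gz"),
               affine = cohort$atlas$affine)

  # ---- manifest --------------------------------------------------------
  outputs <- c("history.csv", "predictions.csv", "metrics.json",
               "interpretation.json", "clusters.csv", "tmap.nii.gz")
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("slicenet")),
    outputs = lapply(setNames(nm = outputs), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
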