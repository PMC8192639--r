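#' Compute regional SUVRs against a reference region
#'
#' The standardized uptake value ratio of a region is the mean intensity
#' over its voxels divided by the mean intensity over the reference region
#' (the cerebellum for amyloid tracers, chosen for its low amyloid
#' deposition). A composite SUVR over the union of the target regions is
#' also computed; the florbetapir global rule uses it.
#'
#' @param volume 3-D numeric array.
#' @param atlas `pet_atlas` on the same grid.
#' @param roi_names Target region names (or ids).
#' @param reference_name Denominator region (default `"cerebellum"`).
#' @param tracer Optional tracer tag carried along for reporting.
#' @return A `suvr_result`: list with `roi_suvrs` (named numeric),
#'   `composite`, `reference_name`, `tracer`.
#' @export
compute_roi_suvr <- function(volume, atlas, roi_names,
                             reference_name = "cerebellum",
                             tracer = NULL) {
  stopifnot(length(dim(volume)) == 3)
  if (!all(dim(volume) == dim(atlas$labels)))
    stop("volume and atlas dims differ")
  ref_mask <- region_mask(atlas, reference_name)
  if (!any(ref_mask))
    stop("reference region '", reference_name, "' has no voxels")
  ref_mean <- mean(volume[ref_mask])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference region '", reference_name,
         "' has non-positive mean uptake (", ref_mean, ")")

  ids <- atlas_region_id(atlas, roi_names)
  nm <- atlas$regions$name[match(ids, atlas$regions$id)]
  suvrs <- vapply(ids, function(id) {
    m <- atlas$labels == id
    if (!any(m)) stop("ROI '", nm[match(id, ids)], "' has no voxels")
    mean(volume[m]) / ref_mean
  }, numeric(1))
  names(suvrs) <- nm
  union_mask <- array(atlas$labels %in% ids, dim(atlas$labels))
  composite <- mean(volume[union_mask]) / ref_mean

  structure(list(roi_suvrs = suvrs, composite = composite,
                 reference_name = reference_name, tracer = tracer),
            class = "suvr_result")
}

#' @export
print.suvr_result <- function(x, digits = 3, ...) {
  cat("SUVR (reference: ", x$reference_name,
      if (!is.null(x$tracer)) paste0(", tracer: ", x$tracer), ")\n", sep = "")
  print(round(x$roi_suvrs, digits))
  cat("composite:", round(x$composite, digits), "\n")
  invisible(x)
}

#' Tracer-specific amyloid positivity rules
#'
#' Built-in rules: florbetapir — positive when the global (composite)
#' SUVR exceeds 1.11; PiB — positive when the SUVR exceeds 1.4 in at
#' least one of the four target regions; florbetaben — the same any-of
#' rule at 1.478. All comparisons are strict: a SUVR exactly at the
#' threshold is negative.
#'
#' @param tracer One of `"florbetapir"`, `"pib"`, `"florbetaben"`.
#' @param threshold,mode,roi_names Optional overrides of the built-in
#'   rule; `roi_names` restricts an `any_of_rois` rule to named regions
#'   (default: all regions present in the SUVR result).
#' @return A `positivity_rule`.
#' @export
positivity_rule <- function(tracer = c("florbetapir", "pib", "florbetaben"),
                            threshold = NULL, mode = NULL,
                            roi_names = NULL) {
  tracer <- match.arg(tracer)
  defaults <- list(
    florbetapir = list(threshold = 1.11, mode = "global"),
    pib = list(threshold = 1.4, mode = "any_of_rois"),
    florbetaben = list(threshold = 1.478, mode = "any_of_rois")
  )[[tracer]]
  threshold <- threshold %||% defaults$threshold
  mode <- mode %||% defaults$mode
  if (!mode %in% c("global", "any_of_rois")) stop("unknown rule mode: ", mode)
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(tracer = tracer, threshold = threshold, mode = mode,
                 roi_names = roi_names),
            class = "positivity_rule")
}

#' @export
print.positivity_rule <- function(x, ...) {
  cat("positivity_rule: ", x$tracer, ", ",
      if (x$mode == "global") "global composite SUVR"
      else "any target ROI SUVR",
      " > ", x$threshold, " (strict)\n", sep = "")
  invisible(x)
}

#' Apply a positivity rule to a SUVR result
#'
#' @param suvr_result A [compute_roi_suvr()] result.
#' @param rule A [positivity_rule()].
#' @return `1L` (positive) or `0L` (negative). The comparison is strict
#'   `>`; boundary equality is negative.
#' @examples
#' s <- structure(list(roi_suvrs = c(a = 1.39, b = 1.41), composite = 1.4,
#'   reference_name = "cerebellum"), class = "suvr_result")
#' classify_positivity(s, positivity_rule("pib", roi_names = c("a", "b")))
#' @export
classify_positivity <- function(suvr_result, rule) {
  stopifnot(inherits(suvr_result, "suvr_result"),
            inherits(rule, "positivity_rule"))
  if (rule$mode == "global") {
    return(as.integer(suvr_result$composite > rule$threshold))
  }
  rois <- rule$roi_names %||% names(suvr_result$roi_suvrs)
  missing <- setdiff(rois, names(suvr_result$roi_suvrs))
  if (length(missing))
    stop("rule ROI(s) missing from SUVR result: ",
         paste(missing, collapse = ", "))
  as.integer(max(suvr_result$roi_suvrs[rois]) > rule$threshold)
}

#' SUVR-based labels for a whole cohort
#'
#' Computes per-subject target-ROI SUVRs and applies a positivity rule,
#' returning one row per subject in the CSV-friendly layout
#' `subject_id`, `tracer`, one column per ROI SUVR, `status`.
#'
#' @param cohort A `pet_cohort` (typically from
#'   [generate_amyloid_cohort()]).
#' @param rule A [positivity_rule()].
#' @param roi_names Target regions; defaults to the cohort's generating
#'   target ROIs when present.
#' @param reference_name Reference region (default `"cerebellum"`).
#' @return Data frame of SUVRs and binary `status`.
#' @export
label_amyloid_cohort <- function(cohort, rule, roi_names = NULL,
                                 reference_name = "cerebellum") {
  stopifnot(inherits(cohort, "pet_cohort"))
  roi_names <- roi_names %||% cohort$target_rois
  if (is.null(roi_names)) stop("roi_names must be given")
  rows <- lapply(seq_along(cohort$volumes), function(i) {
    s <- compute_roi_suvr(cohort$volumes[[i]], cohort$atlas, roi_names,
                          reference_name, tracer = rule$tracer)
    c(list(subject_id = cohort$meta$subject_id[i], tracer = rule$tracer),
      as.list(s$roi_suvrs),
      list(status = classify_positivity(s, rule)))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
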