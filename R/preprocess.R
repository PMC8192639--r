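#' Reference-region intensity normalization
#'
#' Divides every voxel by the mean intensity over a named atlas region
#' (the pons by default), the standard FDG PET scaling that removes
#' subject-level global uptake differences. The reference-region mean of
#' the output equals 1, and the operation is idempotent and invariant to
#' positive rescaling of the input.
#'
#' @param volume 3-D numeric array.
#' @param atlas `pet_atlas` on the same grid.
#' @param reference_name Region name used as denominator (default
#'   `"pons"`).
#' @return Normalized array, same dimensions, attributes preserved.
#' @export
normalize_by_reference <- function(volume, atlas, reference_name = "pons") {
  stopifnot(length(dim(volume)) == 3)
  if (!all(dim(volume) == dim(atlas$labels)))
    stop("volume and atlas dims differ")
  mask <- region_mask(atlas, reference_name)
  if (!any(mask))
    stop("reference region '", reference_name, "' has no voxels")
  m <- mean(volume[mask])
  if (!is.finite(m) || m <= 0)
    stop("reference region '", reference_name,
         "' has non-positive mean intensity (", m, ")")
  volume / m
}

#' Decompose a volume into its orthogonal slice stack
#'
#' Returns every sagittal (`x`-index), coronal (`y`-index) and axial
#' (`z`-index) plane of a 3-D volume, in deterministic order: all sagittal
#' slices by ascending index, then coronal, then axial. An MNI-shaped
#' `91 x 109 x 91` volume yields `91 + 109 + 91 = 291` planes — one per
#' network submodule. Indices are 1-based throughout the package.
#'
#' @param volume 3-D numeric array.
#' @return A `slice_stack`: list with `slices` (list of matrices), `axis`
#'   (character per slice), `index` (integer per slice) and `counts`
#'   (named per-axis totals).
#' @examples
#' st <- extract_slices(array(rnorm(4 * 5 * 6), c(4, 5, 6)))
#' st$counts  # 4 sagittal, 5 coronal, 6 axial
#' @export
extract_slices <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3, all(d >= 1))
  sag <- lapply(seq_len(d[1]), function(i) volume[i, , , drop = TRUE])
  cor <- lapply(seq_len(d[2]), function(j) volume[, j, , drop = TRUE])
  axi <- lapply(seq_len(d[3]), function(k) volume[, , k, drop = TRUE])
  structure(list(
    slices = c(sag, cor, axi),
    axis = rep(c("sagittal", "coronal", "axial"), d),
    index = c(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])),
    counts = c(sagittal = d[1], coronal = d[2], axial = d[3]),
    dims = d
  ), class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat("slice_stack: ", length(x$slices), " slices (",
      paste(x$counts, collapse = " + "), ") from a ",
      paste(x$dims, collapse = " x "), " volume\n", sep = "")
  invisible(x)
}

#' Rebuild a volume from one axis of a slice stack
#'
#' Inverse of [extract_slices()] for a single axis; re-stacking the
#' sagittal (or coronal, or axial) planes reproduces the original volume
#' exactly.
#'
#' @param stack A `slice_stack`.
#' @param axis Which axis family to stack.
#' @return 3-D array with the stack's original dimensions.
#' @export
restack_slices <- function(stack, axis = c("sagittal", "coronal", "axial")) {
  axis <- match.arg(axis)
  sel <- stack$axis == axis
  slices <- stack$slices[sel]
  d <- stack$dims
  out <- array(NA_real_, d)
  ord <- order(stack$index[sel])
  slices <- slices[ord]
  for (i in seq_along(slices)) {
    if (axis == "sagittal") out[i, , ] <- slices[[i]]
    else if (axis == "coronal") out[, i, ] <- slices[[i]]
    else out[, , i] <- slices[[i]]
  }
  out
}
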