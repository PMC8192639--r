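#' Read / write a 3-D volume as NIfTI
#'
#' Thin wrappers over the RNifti reader and writer. Only rank-3 images
#' are accepted; the voxel-to-mm affine travels as the `"affine"`
#' attribute of the returned array. Data are stored as doubles, so a
#' write/read round trip preserves values to floating tolerance, and
#' gzipped (`.nii.gz`) and plain (`.nii`) files load identically.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume`: a 3-D array with an `affine` attribute.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop("expected a 3-D volume, got ", length(dim(arr)),
         " dimension(s) in ", path)
  aff <- tryCatch(unclass(RNifti::xform(img)), error = function(e) diag(4))
  out <- array(as.numeric(arr), dim(arr))
  attr(out, "affine") <- aff
  out
}

#' @rdname read_volume
#' @param volume 3-D numeric array.
#' @param affine Optional 4x4 voxel-to-mm matrix (defaults to the
#'   array's `affine` attribute, else identity spacing).
#' @export
write_volume <- function(volume, path, affine = NULL) {
  stopifnot(length(dim(volume)) == 3)
  affine <- affine %||% attr(volume, "affine")
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  if (!is.null(affine)) {
    RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
    RNifti::qform(img) <- structure(affine, code = 2L)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write / read a cohort directory
#'
#' Lays a `pet_cohort` out on disk in plain interoperable formats:
#' one NIfTI volume per subject (`<subject_id>.nii.gz`), the label table
#' as `labels.csv` (`subject_id`, `label`, `subgroup`), and the atlas as
#' `atlas.nii.gz` plus `atlas_regions.csv`.
#'
#' @param cohort A `pet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `pet_cohort` (without the generating config).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pet_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aff <- cohort$atlas$affine
  for (i in seq_along(cohort$volumes))
    write_volume(cohort$volumes[[i]],
                 file.path(dir, paste0(cohort$meta$subject_id[i],
                                       ".nii.gz")), affine = aff)
  write.csv(cohort$meta, file.path(dir, "labels.csv"), row.names = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  atlas <- read_atlas(file.path(dir, "atlas"))
  volumes <- lapply(meta$subject_id, function(id)
    read_volume(file.path(dir, paste0(id, ".nii.gz"))))
  structure(list(volumes = volumes, meta = meta, atlas = atlas,
                 config = NULL),
            class = "pet_cohort")
}
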