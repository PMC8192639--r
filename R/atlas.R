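#' Generate a toy brain atlas
#'
#' Builds a small integer-labelled parcellation for testing and simulation:
#' an ellipsoidal "brain" whose inferior cap is split into two reference
#' regions named `pons` and `cerebellum`, and whose remaining voxels are
#' partitioned into `n_cortical_regions` contiguous parcels by a seeded
#' k-means tessellation of voxel coordinates. It stands in for an
#' anatomical parcellation such as AAL at whatever grid size the caller
#' asks for; it has no anatomical realism beyond the label structure the
#' downstream analyses need.
#'
#' @param dims Integer vector `(nx, ny, nz)` of voxel counts, each `>= 8`.
#' @param n_cortical_regions Number of cortical parcels, `>= 2`.
#' @param seed RNG seed controlling the tessellation.
#' @param min_voxels Minimum voxels any region must contain (default 60).
#' @return A `pet_atlas`: list with `labels` (3-D integer array, 0 =
#'   background, `1..n` cortical, then pons and cerebellum), `regions`
#'   (data frame `id`, `name`, `is_reference`), and `affine` (voxel-to-mm,
#'   2 mm isotropic, origin at the volume centre).
#' @examples
#' atl <- generate_toy_atlas(c(24, 28, 24), 6)
#' table(atl$labels)[-1]
#' @export
generate_toy_atlas <- function(dims, n_cortical_regions, seed = 1L,
                               min_voxels = 60L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (any(dims < 8))
    stop("all dims must be >= 8; got (", paste(dims, collapse = ", "), ")")
  n <- as.integer(n_cortical_regions)
  if (n < 2) stop("n_cortical_regions must be >= 2")

  ctr <- (dims + 1) / 2
  semi <- 0.45 * dims
  ex <- ((seq_len(dims[1]) - ctr[1]) / semi[1])^2
  ey <- ((seq_len(dims[2]) - ctr[2]) / semi[2])^2
  ez <- ((seq_len(dims[3]) - ctr[3]) / semi[3])^2
  r2 <- outer(outer(ex, ey, "+"), ez, "+")
  brain <- r2 <= 1

  # inferior cap -> reference regions, rest -> cortical parcels
  zcut <- max(2L, floor(0.25 * dims[3]))
  coords <- which(brain, arr.ind = TRUE)
  inferior <- coords[, 3] <= zcut
  ref <- coords[inferior, , drop = FALSE]
  cort <- coords[!inferior, , drop = FALSE]

  pons_sel <- ref[, 2] > ctr[2]  # anterior half of the cap
  n_pons <- sum(pons_sel)
  n_cereb <- sum(!pons_sel)
  if (n_pons < min_voxels || n_cereb < min_voxels)
    stop("dims (", paste(dims, collapse = ", "), ") too small: reference ",
         "regions would have ", n_pons, " and ", n_cereb,
         " voxels; need >= ", min_voxels, " each")
  if (nrow(cort) < n * min_voxels)
    stop("dims (", paste(dims, collapse = ", "), ") too small to fit ", n,
         " cortical regions of >= ", min_voxels, " voxels (only ",
         nrow(cort), " cortical voxels available)")

  set.seed(seed)
  km <- NULL
  for (try in 1:5) {
    km_try <- suppressWarnings(
      stats::kmeans(cort, centers = n, iter.max = 25L, nstart = 1L))
    if (min(tabulate(km_try$cluster, n)) >= min_voxels) { km <- km_try; break }
  }
  if (is.null(km))
    stop("could not tessellate ", n, " cortical regions of >= ", min_voxels,
         " voxels inside dims (", paste(dims, collapse = ", "), ")")

  labels <- array(0L, dims)
  labels[cort] <- km$cluster
  labels[ref[pons_sel, , drop = FALSE]] <- n + 1L
  labels[ref[!pons_sel, , drop = FALSE]] <- n + 2L

  regions <- data.frame(
    id = seq_len(n + 2L),
    name = c(sprintf("cortical_%02d", seq_len(n)), "pons", "cerebellum"),
    is_reference = c(rep(FALSE, n), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  affine <- diag(c(2, 2, 2, 1))
  affine[1:3, 4] <- -ctr * 2

  structure(list(labels = labels, regions = regions, affine = affine),
            class = "pet_atlas")
}

#' @export
print.pet_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat("pet_atlas: ", paste(d, collapse = " x "), " voxels, ",
      nrow(x$regions), " regions (",
      sum(!x$regions$is_reference), " cortical + ",
      sum(x$regions$is_reference), " reference)\n", sep = "")
  invisible(x)
}

# id of a region given its name (or a validated id)
atlas_region_id <- function(atlas, region) {
  if (is.numeric(region)) {
    if (!all(region %in% atlas$regions$id))
      stop("unknown region id(s): ",
           paste(setdiff(region, atlas$regions$id), collapse = ", "))
    return(as.integer(region))
  }
  m <- match(region, atlas$regions$name)
  if (anyNA(m))
    stop("unknown region name(s): ", paste(region[is.na(m)], collapse = ", "))
  atlas$regions$id[m]
}

#' Logical mask of one or more atlas regions
#'
#' @param atlas A `pet_atlas`.
#' @param region Region name(s) or id(s).
#' @return Logical array matching the atlas grid.
#' @export
region_mask <- function(atlas, region) {
  ids <- atlas_region_id(atlas, region)
  array(atlas$labels %in% ids, dim(atlas$labels))
}

#' Write / read an atlas as NIfTI plus a region table
#'
#' The label volume goes to `<stem>.nii.gz` and the region table to
#' `<stem>_regions.csv` (columns `id`, `name`, `is_reference`).
#'
#' @param atlas A `pet_atlas`.
#' @param stem Path stem (no extension).
#' @return `write_atlas` returns the stem invisibly; `read_atlas` returns a
#'   `pet_atlas`.
#' @export
write_atlas <- function(atlas, stem) {
  write_volume(atlas$labels, paste0(stem, ".nii.gz"), affine = atlas$affine)
  write.csv(atlas$regions, paste0(stem, "_regions.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(stem) {
  vol <- read_volume(paste0(stem, ".nii.gz"))
  regions <- read.csv(paste0(stem, "_regions.csv"), stringsAsFactors = FALSE)
  labels <- array(as.integer(round(vol)), dim(vol))
  structure(list(labels = labels, regions = regions,
                 affine = attr(vol, "affine")),
            class = "pet_atlas")
}
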