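#' Per-axis significant slices from submodule predictions
#'
#' For every slice submodule, compares its predicted probabilities
#' between the subjects the MODEL classified positive versus negative
#' with a two-sample t test (two-tailed, Welch by default; set
#' `var.equal = TRUE` for the pooled-variance flavour) and returns the
#' slice indices with `p < alpha`, partitioned by axis. Grouping uses the
#' model's final classification, not the ground-truth labels. Submodules
#' whose outputs are constant in both groups are excluded (zero-variance
#' guard). No multiple-testing correction is applied across submodules.
#'
#' @param predictions A `slicenet_predictions` object from
#'   [predict.slicenet()], or any data frame with a `class` column plus
#'   `submodule_probabilities`/`axis`/`index` attributes.
#' @param alpha Test level (default 0.05).
#' @param var.equal Pooled-variance t test instead of Welch.
#' @return List with `sig_x`, `sig_y`, `sig_z` (sorted significant
#'   sagittal/coronal/axial slice indices), `pvals` (per-slice data
#'   frame), and `alpha`.
#' @export
submodule_significance <- function(predictions, alpha = 0.05,
                                   var.equal = FALSE) {
  P <- attr(predictions, "submodule_probabilities")
  axis <- attr(predictions, "axis")
  index <- attr(predictions, "index")
  if (is.null(P)) stop("predictions carry no submodule probabilities")
  cls <- predictions$class
  n_pos <- sum(cls == 1L)
  n_neg <- sum(cls == 0L)
  if (n_pos < 2)
    stop("predicted-positive group has ", n_pos,
         " member(s); need at least 2 per class")
  if (n_neg < 2)
    stop("predicted-negative group has ", n_neg,
         " member(s); need at least 2 per class")

  pv <- apply(P, 1, function(row) {
    a <- row[cls == 1L]
    b <- row[cls == 0L]
    if (sd(a) == 0 && sd(b) == 0) return(NA_real_)
    tryCatch(t.test(a, b, var.equal = var.equal)$p.value,
             error = function(e) NA_real_)
  })
  sig <- !is.na(pv) & pv < alpha
  pick <- function(ax) sort(index[axis == ax & sig])
  list(sig_x = pick("sagittal"), sig_y = pick("coronal"),
       sig_z = pick("axial"),
       pvals = data.frame(axis = axis, index = index, p = pv,
                          stringsAsFactors = FALSE),
       alpha = alpha)
}

#' Cartesian point cloud from per-axis significant slices
#'
#' A voxel `(x, y, z)` is plotted when the x-th sagittal, y-th coronal
#' and z-th axial planes are all significant, i.e. the point set is the
#' Cartesian product of the three slice sets and its size is the product
#' of their sizes. With two significant slices per axis, 8 points are
#' plotted; sets of sizes 20, 27 and 24 give 12,960 points. This
#' over-plots by construction — only some of the points reflect truly
#' discriminative locations — which is why the ROI point threshold of
#' [extract_roi_clusters()] exists.
#'
#' @param sig_x,sig_y,sig_z Integer vectors of significant slice indices
#'   (1-based; empty sets allowed).
#' @return Integer matrix with columns `x`, `y`, `z`, one row per point.
#' @examples
#' nrow(cartesian_points(c(46, 51), c(34, 64, 66), c(37, 45)))  # 12
#' @export
cartesian_points <- function(sig_x, sig_y, sig_z) {
  if (!length(sig_x) || !length(sig_y) || !length(sig_z))
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  g <- expand.grid(x = as.integer(sig_x), y = as.integer(sig_y),
                   z = as.integer(sig_z), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Atlas regions receiving more than a minimum number of points
#'
#' Tallies the Cartesian points per atlas region (background label 0 is
#' excluded) and returns the regions whose count strictly exceeds
#' `min_points`, sorted by count. The default threshold of 50 matches
#' the voxel-wise cluster-extent threshold; for toy volumes with far
#' fewer slices, scale it down.
#'
#' @param points Matrix of `(x, y, z)` voxel coordinates (1-based).
#' @param atlas A `pet_atlas` whose grid bounds all points.
#' @param min_points Strict lower bound on the per-region point count.
#' @return A `roi_point_counts` list: `counts` (data frame `id`, `name`,
#'   `count` for all regions hit), `surviving` (subset with
#'   `count > min_points`), `n_points`, `background` (points on label 0),
#'   `min_points`.
#' @export
extract_roi_clusters <- function(points, atlas, min_points = 50L) {
  stopifnot(inherits(atlas, "pet_atlas"))
  points <- as.matrix(points)
  d <- dim(atlas$labels)
  if (nrow(points)) {
    if (any(points < 1) || any(points[, 1] > d[1]) ||
        any(points[, 2] > d[2]) || any(points[, 3] > d[3]))
      stop("point(s) outside the atlas volume bounds (",
           paste(d, collapse = " x "), ")")
  }
  labs <- if (nrow(points)) atlas$labels[points] else integer(0)
  background <- sum(labs == 0L)
  labs <- labs[labs != 0L]
  tab <- table(labs)
  counts <- data.frame(
    id = as.integer(names(tab)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  counts$name <- atlas$regions$name[match(counts$id, atlas$regions$id)]
  counts <- counts[order(-counts$count), c("id", "name", "count")]
  rownames(counts) <- NULL
  surviving <- counts[counts$count > min_points, , drop = FALSE]
  structure(list(counts = counts, surviving = surviving,
                 n_points = nrow(points), background = background,
                 min_points = min_points),
            class = "roi_point_counts")
}

#' @export
print.roi_point_counts <- function(x, ...) {
  cat("roi_point_counts: ", x$n_points, " points, ", x$background,
      " on background; ", nrow(x$surviving), " region(s) with > ",
      x$min_points, " points\n", sep = "")
  if (nrow(x$surviving)) print(x$surviving)
  invisible(x)
}

#' Slice-significance interpretation of a fitted model
#'
#' The full interpretation chain: per-submodule two-sample t tests
#' between the model's predicted classes, the Cartesian point cloud of
#' the per-axis significant slices, and the atlas regions that collect
#' strictly more than `min_points` points.
#'
#' @inheritParams submodule_significance
#' @inheritParams extract_roi_clusters
#' @param atlas A `pet_atlas` on the model's grid.
#' @return A `slicenet_significance`: the [submodule_significance()]
#'   fields plus `points`, `roi_counts`, `surviving_rois`, `min_points`.
#' @export
interpret_slicenet <- function(predictions, atlas, alpha = 0.05,
                               min_points = 50L, var.equal = FALSE) {
  sig <- submodule_significance(predictions, alpha, var.equal)
  pts <- cartesian_points(sig$sig_x, sig$sig_y, sig$sig_z)
  rc <- extract_roi_clusters(pts, atlas, min_points)
  structure(c(sig, list(points = pts, roi_counts = rc$counts,
                        surviving_rois = rc$surviving,
                        background_points = rc$background,
                        min_points = min_points)),
            class = "slicenet_significance")
}

#' @export
print.slicenet_significance <- function(x, ...) {
  cat("slicenet_significance (alpha = ", x$alpha, ")\n", sep = "")
  cat("  significant slices: ", length(x$sig_x), " sagittal, ",
      length(x$sig_y), " coronal, ", length(x$sig_z), " axial\n",
      sep = "")
  cat("  Cartesian points:   ", nrow(x$points), "\n", sep = "")
  cat("  surviving ROIs (> ", x$min_points, " points): ",
      if (nrow(x$surviving_rois))
        paste(x$surviving_rois$name, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}
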