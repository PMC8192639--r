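#' Voxel-wise two-sample t map
#'
#' Computes, at every masked voxel, the two-sample t statistic and
#' two-tailed p value between the amyloid-positive (`label == 1`) and
#' negative groups. Positive t means the positive group has the higher
#' mean. The pooled-variance test is the default (the classical
#' two-sample imaging design); `var.equal = FALSE` gives Welch with
#' per-voxel Satterthwaite degrees of freedom. Voxels with zero variance
#' in both groups are removed from the mask and counted.
#'
#' @param volumes List of co-dimensional 3-D arrays.
#' @param labels Binary vector, at least 2 subjects per class.
#' @param mask Logical array of voxels to analyze (default: all voxels;
#'   pass e.g. `atlas$labels > 0` for a brain mask).
#' @param var.equal Pooled (default) vs Welch variance.
#' @return A `stat_map`: `t_map` and `p_map` (arrays, `NA` outside the
#'   final mask), `df`, `mask`, `n_zero_var`, group sizes, and the masked
#'   data matrix (used by the permutation correction).
#' @export
voxelwise_ttest <- function(volumes, labels, mask = NULL,
                            var.equal = TRUE) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2)
    stop("need at least 2 subjects per class (got ", n1, " positive, ",
         n0, " negative)")
  d <- dim(volumes[[1]])
  for (v in volumes)
    if (!all(dim(v) == d)) stop("volumes are not co-dimensional")
  mask <- mask %||% array(TRUE, d)
  if (!all(dim(mask) == d)) stop("mask dims differ from volume dims")

  mv <- as.vector(mask)
  Y <- vapply(volumes, function(v) as.vector(v)[mv],
              numeric(sum(mv)))          # V x n
  g1 <- labels == 1L
  v1 <- rowVars(Y[, g1, drop = FALSE])
  v0 <- rowVars(Y[, !g1, drop = FALSE])
  zero <- (v1 + v0) == 0
  n_zero_var <- sum(zero)

  m1 <- rowMeans(Y[, g1, drop = FALSE])
  m0 <- rowMeans(Y[, !g1, drop = FALSE])
  if (var.equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    tt <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(tt))
  } else {
    se2 <- v1 / n1 + v0 / n0
    tt <- (m1 - m0) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  tt[zero] <- NA_real_
  pp <- 2 * pt(-abs(tt), df)

  final_mask <- mask
  final_mask[mv][zero] <- FALSE
  t_map <- array(NA_real_, d)
  p_map <- array(NA_real_, d)
  t_map[final_mask] <- tt[!zero]
  p_map[final_mask] <- pp[!zero]

  structure(list(t_map = t_map, p_map = p_map,
                 df = if (var.equal) n1 + n0 - 2 else
                   array_from_mask(df, final_mask, mv, zero, d),
                 mask = final_mask, n_zero_var = n_zero_var,
                 n1 = n1, n0 = n0, var.equal = var.equal,
                 data = Y[!zero, , drop = FALSE], labels = labels),
            class = "stat_map")
}

array_from_mask <- function(vals, final_mask, mv, zero, d) {
  a <- array(NA_real_, d)
  a[final_mask] <- vals[!zero]
  a
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map: ", sum(x$mask), " voxels analyzed (",
      x$n1, " vs ", x$n0, " subjects, ",
      if (x$var.equal) "pooled" else "Welch", " t), ",
      x$n_zero_var, " zero-variance voxel(s) excluded\n", sep = "")
  invisible(x)
}

# fast pooled/Welch t for permutation: Y is V x n
perm_tstat <- function(Y, labels, var.equal) {
  g1 <- labels == 1L
  n1 <- sum(g1); n0 <- sum(!g1)
  v1 <- rowVars(Y[, g1, drop = FALSE])
  v0 <- rowVars(Y[, !g1, drop = FALSE])
  m1 <- rowMeans(Y[, g1, drop = FALSE])
  m0 <- rowMeans(Y[, !g1, drop = FALSE])
  if (var.equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
  } else {
    (m1 - m0) / sqrt(v1 / n1 + v0 / n0)
  }
}

#' Threshold a t map and extract voxel clusters
#'
#' Binarizes the statistic map at a significance threshold — uncorrected
#' (`"none"`, e.g. p < 0.001), Bonferroni, or permutation max-T
#' family-wise error — then labels connected components separately for
#' positive and negative t signs and discards components whose size is
#' not strictly greater than `k` voxels.
#'
#' @param stat_map A [voxelwise_ttest()] result.
#' @param p_threshold Significance level applied to the (corrected)
#'   p value.
#' @param correction `"none"`, `"bonferroni"`, or `"permutation"`
#'   (max-T: the label vector is permuted `n_perm` times and each
#'   voxel's corrected p is the fraction of permutation max |t| values
#'   at least as large as its observed |t|).
#' @param k Cluster-extent threshold; components survive only with size
#'   `> k` (strict).
#' @param connectivity 6, 18 (default) or 26.
#' @param n_perm,perm_seed Permutation count and RNG seed for
#'   `correction = "permutation"`.
#' @return A `cluster_result`: `clusters` (data frame with `id`, `sign`,
#'   `size`, `peak_t`, `peak_x/y/z`), `voxels` (list of voxel-coordinate
#'   matrices), `cluster_map` (labelled array), and the threshold spec.
#' @export
threshold_and_cluster <- function(stat_map, p_threshold = 0.001,
                                  correction = c("none", "bonferroni",
                                                 "permutation"),
                                  k = 50L, connectivity = 18L,
                                  n_perm = 500L, perm_seed = 1L) {
  stopifnot(inherits(stat_map, "stat_map"))
  correction <- match.arg(correction)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(stat_map$t_map)
  mask <- stat_map$mask

  pass <- array(FALSE, d)
  if (correction == "none") {
    pass[mask] <- stat_map$p_map[mask] < p_threshold
  } else if (correction == "bonferroni") {
    V <- sum(mask)
    pass[mask] <- pmin(stat_map$p_map[mask] * V, 1) < p_threshold
  } else {
    set.seed(perm_seed)
    Y <- stat_map$data
    labs <- stat_map$labels
    maxT <- vapply(seq_len(n_perm), function(i) {
      tp <- perm_tstat(Y, sample(labs), stat_map$var.equal)
      max(abs(tp), na.rm = TRUE)
    }, numeric(1))
    tobs <- abs(stat_map$t_map[mask])
    p_corr <- vapply(tobs, function(t0) mean(maxT >= t0), numeric(1))
    pass[mask] <- p_corr < p_threshold
  }

  clusters <- list()
  voxels <- list()
  cluster_map <- array(0L, d)
  next_id <- 0L
  for (sgn in c(1, -1)) {
    m <- pass & !is.na(stat_map$t_map) & (sgn * stat_map$t_map > 0)
    if (!any(m)) next
    lab <- .label_components(as.vector(m), as.integer(d),
                             as.integer(connectivity))
    sizes <- tabulate(lab[lab > 0L])
    for (cid in which(sizes > k)) {
      next_id <- next_id + 1L
      vox <- which(lab == cid, arr.ind = TRUE)
      tv <- stat_map$t_map[vox]
      pk <- which.max(abs(tv))
      clusters[[next_id]] <- data.frame(
        id = next_id, sign = sgn, size = nrow(vox),
        peak_t = tv[pk], peak_x = vox[pk, 1], peak_y = vox[pk, 2],
        peak_z = vox[pk, 3])
      voxels[[next_id]] <- vox
      cluster_map[vox] <- next_id
    }
  }
  tab <- if (length(clusters)) {
    tb <- do.call(rbind, clusters)
    rownames(tb) <- NULL
    tb
  } else
    data.frame(id = integer(0), sign = numeric(0), size = integer(0),
               peak_t = numeric(0), peak_x = integer(0),
               peak_y = integer(0), peak_z = integer(0))
  structure(list(clusters = tab, voxels = voxels,
                 cluster_map = cluster_map,
                 threshold_spec = list(p_threshold = p_threshold,
                                       correction = correction, k = k,
                                       connectivity = connectivity)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  ts <- x$threshold_spec
  cat("cluster_result: p < ", ts$p_threshold, " (", ts$correction,
      "), k > ", ts$k, ", ", ts$connectivity, "-connectivity\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}
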