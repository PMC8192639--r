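# build a predictions object by hand: S submodules over a dims grid,
# with optional mean shifts between predicted classes for chosen slices
fake_predictions <- function(dims, n_per_class, shift_slices = list(),
                             shift = 0.5, sd = 0.02, seed = 1) {
  set.seed(seed)
  axes <- rep(c("sagittal", "coronal", "axial"), dims)
  index <- c(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
  S <- length(axes)
  n <- 2 * n_per_class
  cls <- rep(c(1L, 0L), each = n_per_class)
  P <- matrix(rnorm(S * n, 0.5, sd), S, n)
  for (ax in names(shift_slices)) {
    for (ix in shift_slices[[ax]]) {
      row <- which(axes == ax & index == ix)
      P[row, cls == 1L] <- P[row, cls == 1L] + shift
    }
  }
  P <- pmin(pmax(P, 0), 1)
  out <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    probability = cls * 0.8 + 0.1, class = cls)
  attr(out, "submodule_probabilities") <- P
  attr(out, "axis") <- axes
  attr(out, "index") <- index
  class(out) <- c("slicenet_predictions", "data.frame")
  out
}

test_that("injected group shifts are the slices found significant", {
  pr <- fake_predictions(c(16, 16, 16), 10,
                         shift_slices = list(sagittal = c(3, 7),
                                             coronal = 2,
                                             axial = c(5, 9)),
                         shift = 0.4, sd = 0.02, seed = 6)
  sig <- submodule_significance(pr, alpha = 1e-6)
  expect_equal(sig$sig_x, c(3L, 7L))
  expect_equal(sig$sig_y, 2L)
  expect_equal(sig$sig_z, c(5L, 9L))

  # p-value for one shifted slice equals a direct Welch t test
  P <- attr(pr, "submodule_probabilities")
  row <- which(attr(pr, "axis") == "sagittal" & attr(pr, "index") == 3)
  direct <- t.test(P[row, pr$class == 1L], P[row, pr$class == 0L])$p.value
  expect_equal(sig$pvals$p[row], direct)
})

test_that("constant submodule outputs are excluded, not significant", {
  pr <- fake_predictions(c(16, 16, 16), 6, seed = 2)
  P <- attr(pr, "submodule_probabilities")
  P[5, ] <- 0.5  # zero variance in both groups
  attr(pr, "submodule_probabilities") <- P
  sig <- submodule_significance(pr, alpha = 0.5)
  expect_true(is.na(sig$pvals$p[5]))
  expect_false(5L %in% sig$sig_x)
})

test_that("a predicted class with fewer than two members fails by name", {
  pr <- fake_predictions(c(16, 16, 16), 4, seed = 3)
  pr$class <- c(1L, rep(0L, 7))
  expect_error(submodule_significance(pr), "predicted-positive")
  pr$class <- c(rep(1L, 7), 0L)
  expect_error(submodule_significance(pr), "predicted-negative")
})

test_that("under the null the significant-slice rate is near alpha", {
  pr <- fake_predictions(c(100, 100, 100), 15, seed = 9)  # 300 null tests
  sig <- submodule_significance(pr, alpha = 0.05)
  rate <- (length(sig$sig_x) + length(sig$sig_y) + length(sig$sig_z)) / 300
  expect_lt(rate, 0.11)  # 0.05 + ~4 binomial SDs
})

test_that("Cartesian point clouds reproduce the worked examples", {
  # two significant slices per axis -> 8 points
  expect_equal(nrow(cartesian_points(c(10, 11), c(20, 21), c(30, 31))), 8L)
  # x = {46, 51}, y = {34, 64, 66}, z = {37, 45} -> 12 points
  pts <- cartesian_points(c(46, 51), c(34, 64, 66), c(37, 45))
  expect_equal(nrow(pts), 12L)
  expect_true(all(c(46, 34, 37) == pts[1, ]))
  expect_equal(nrow(unique(pts)), 12L)
  # 20 x 27 x 24 significant slices -> 12,960 points
  expect_equal(nrow(cartesian_points(1:20, 1:27, 1:24)), 12960L)
  # empty set on any axis -> no points
  expect_equal(nrow(cartesian_points(integer(0), 1:3, 1:3)), 0L)
})

test_that("ROI point counts equal a brute-force tally and threshold strictly", {
  atl <- tiny_atlas()
  set.seed(11)
  pts <- cbind(x = sample(16, 400, TRUE), y = sample(16, 400, TRUE),
               z = sample(16, 400, TRUE))
  rc <- extract_roi_clusters(pts, atl, min_points = 10)
  # oracle: per-point label lookup, counted by hand
  labs <- vapply(seq_len(nrow(pts)),
                 function(i) atl$labels[pts[i, 1], pts[i, 2], pts[i, 3]],
                 integer(1))
  for (k in seq_len(nrow(rc$counts)))
    expect_equal(rc$counts$count[k], sum(labs == rc$counts$id[k]))
  expect_equal(rc$background, sum(labs == 0L))
  expect_equal(sum(rc$counts$count) + rc$background, nrow(pts))
  expect_true(all(rc$surviving$count > 10))

  # strictness at the boundary: exactly min_points is excluded
  lab <- array(0L, c(8, 8, 8)); lab[1:4, 1:4, 1:4] <- 1L
  atl2 <- hand_atlas(lab, "box")
  in_box <- which(lab == 1L, arr.ind = TRUE)
  rc50 <- extract_roi_clusters(in_box[1:50, ], atl2, min_points = 50)
  expect_equal(nrow(rc50$surviving), 0L)
  rc51 <- extract_roi_clusters(in_box[1:51, ], atl2, min_points = 50)
  expect_equal(rc51$surviving$name, "box")
})

test_that("points on background only, and out-of-bounds points, behave", {
  lab <- array(0L, c(8, 8, 8)); lab[8, 8, 8] <- 1L
  atl <- hand_atlas(lab, "spot")
  rc <- extract_roi_clusters(cbind(1:3, 1, 1), atl, min_points = 0)
  expect_equal(nrow(rc$counts), 0L)
  expect_equal(rc$background, 3L)
  expect_error(extract_roi_clusters(cbind(9, 1, 1), atl), "bounds")
  expect_error(extract_roi_clusters(cbind(0, 1, 1), atl), "bounds")
})

test_that("end-to-end interpretation on a trained model keeps its invariants", {
  tt <- tiny_trained()
  pr <- predict(tt$fit, tt$volumes, subject_ids = tt$cohort$meta$subject_id)
  # the separable fixture should classify both classes with >= 2 members
  expect_gte(sum(pr$class == 1L), 2L)
  expect_gte(sum(pr$class == 0L), 2L)
  res <- interpret_slicenet(pr, tt$atlas, alpha = 0.05, min_points = 5)
  expect_equal(nrow(res$points),
               length(res$sig_x) * length(res$sig_y) * length(res$sig_z))
  expect_equal(sum(res$roi_counts$count) + res$background_points,
               nrow(res$points))
  expect_true(all(res$surviving_rois$count > 5))
})
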