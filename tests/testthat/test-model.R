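test_that("submodule geometry follows the conv/pool arithmetic", {
  cfg <- slicenet_config(c(32, 32, 32))
  sub <- build_submodule(c(32, 32), cfg)
  # 32 -> 16 -> 8 -> 4 -> 2 through four pools; 2*2*128 = 512 features
  expect_equal(sub$feat_shape, c(2L, 2L, 128L))
  expect_equal(sub$feat_len, 512L)

  cfg2 <- slicenet_config(c(91, 109, 91))
  sub2 <- build_submodule(c(91, 109), cfg2)
  # 91 -> 45 -> 22 -> 11 -> 5 and 109 -> 54 -> 27 -> 13 -> 6 (floor)
  expect_equal(sub2$feat_shape, c(5L, 6L, 128L))

  # convolutions are shape-agnostic: parameter counts differ only in the
  # final fully connected layer
  expect_equal(sub$n_params - (sub$feat_len + 1L),
               sub2$n_params - (sub2$feat_len + 1L))
})

test_that("shapes that cannot survive four poolings are rejected loudly", {
  cfg <- slicenet_config(c(32, 32, 32))
  expect_error(build_submodule(c(12, 32), cfg), ">= 16")
  expect_error(slicenet_config(c(8, 10, 8)), ">= 16")
  expect_error(slicenet_config(c(32, 32, 32), conv_filters = c(8, 8, 8)),
               "length 4")
})

test_that("the model has one independent submodule per slice", {
  cfg <- slicenet_config(c(16, 20, 24), conv_filters = c(2, 2, 2, 2),
                         seed = 4)
  m <- build_model(cfg)
  expect_equal(m$n_submodules, 60L)  # 16 + 20 + 24
  expect_equal(length(m$head$w), 60L)
  expect_equal(sum(m$axis == "sagittal"), 16L)
  expect_equal(sum(m$axis == "coronal"), 20L)
  expect_equal(sum(m$axis == "axial"), 24L)
  # equal slice shapes -> equal parameter counts, but no weight sharing
  sag <- which(m$axis == "sagittal")
  expect_equal(m$submodules[[sag[1]]]$n_params,
               m$submodules[[sag[2]]]$n_params)
  expect_false(identical(m$submodules[[sag[1]]]$par$W1,
                         m$submodules[[sag[2]]]$par$W1))
})

test_that("backpropagated gradients match finite differences", {
  sn <- asNamespace("slicenet")
  set.seed(42)
  sub <- sn$init_submodule_params(c(16L, 20L), c(3L, 4L, 5L, 6L))
  N <- 2L
  X <- array(rnorm(16 * 20 * N), c(16, 20, N))
  ds <- rnorm(N)
  loss_fn <- function(s) sum(sn$forward_sub(s, X, N, training = TRUE)$s * ds)
  fw <- sn$forward_sub(sub, X, N, training = TRUE)
  gr <- sn$backward_sub(sub, fw$cache, ds, N)
  eps <- 1e-6
  # conv biases excluded: batch norm makes their true gradient zero
  for (nm in c("W1", "W3", "g2", "be4", "Wf", "bf")) {
    p <- sub$par[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      s2 <- sub; s2$par[[nm]][i] <- p[i] + eps
      s3 <- sub; s3$par[[nm]][i] <- p[i] - eps
      num <- (loss_fn(s2) - loss_fn(s3)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
    }
  }
  # and conv biases really do receive an (analytically) zero gradient
  expect_lt(max(abs(gr$b1)), 1e-10)
})

test_that("training records history and checkpoints the best epoch", {
  tt <- tiny_trained()
  fit <- tt$fit
  expect_s3_class(fit, "slicenet")
  expect_true(fit$trained)
  expect_equal(nrow(fit$history), 5L)
  expect_equal(fit$checkpoint_epoch, which.min(fit$history$val_loss))
  # loss went down on a separable cohort
  expect_lt(fit$history$train_loss[3], fit$history$train_loss[1])
})

test_that("gradient flows to every submodule on one batch", {
  sn <- asNamespace("slicenet")
  tt <- tiny_trained()
  # fresh (unsaturated) model: every submodule must receive gradient
  m <- build_model(slicenet_config(c(16, 16, 16),
                                   conv_filters = c(4, 8, 8, 8),
                                   seed = 13))
  ids <- 1:4
  y <- tt$cohort$meta$label[ids]
  S <- m$n_submodules
  P <- matrix(0, S, 4)
  caches <- vector("list", S)
  for (s in seq_len(S)) {
    X <- sn$slice_batch(tt$volumes, ids, m$axis[s], m$index[s])
    fw <- sn$forward_sub(m$submodules[[s]], X, 4L, training = TRUE)
    P[s, ] <- fw$s
    caches[[s]] <- fw$cache
  }
  f <- sn$sigmoid(colSums(P * m$head$w) + m$head$b)
  dv <- (f - y) / 4
  dP <- outer(m$head$w, dv)
  blank <- vapply(seq_len(S), function(s)
    sum(abs(sn$slice_batch(tt$volumes, ids, m$axis[s],
                           m$index[s]))) == 0, logical(1))
  nonzero <- vapply(seq_len(S), function(s) {
    g <- sn$backward_sub(m$submodules[[s]], caches[[s]], dP[s, ], 4L)
    # every submodule's output unit sees gradient; conv weights do too
    # except for slices that are identically zero (outside the brain),
    # where dW = X^T dY vanishes by construction
    abs(g$bf) > 0 && (blank[s] || sum(abs(g$W1)) > 0)
  }, logical(1))
  expect_true(all(nonzero))
})

test_that("inference is deterministic, bounded, and strictly thresholded", {
  tt <- tiny_trained()
  p1 <- predict(tt$fit, tt$volumes[1:3])
  p2 <- predict(tt$fit, tt$volumes[1:3])
  expect_identical(p1$probability, p2$probability)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))
  P <- attr(p1, "submodule_probabilities")
  expect_equal(dim(P), c(tt$fit$n_submodules, 3L))
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(p1$class, as.integer(p1$probability > 0.5))

  # a probability of exactly 0.5 is classified negative (strict >)
  cfg <- slicenet_config(c(16, 16, 16), conv_filters = c(2, 2, 2, 2),
                         seed = 1)
  m0 <- build_model(cfg)
  m0$head$w[] <- 0
  m0$head$b <- 0
  p0 <- predict(m0, tt$volumes[1])
  expect_equal(p0$probability, 0.5)
  expect_equal(p0$class, 0L)
})

test_that("prediction rejects volumes of the wrong shape", {
  tt <- tiny_trained()
  expect_error(predict(tt$fit, array(0, c(16, 16, 18))),
               "do not match")
})

test_that("a single-class training set is refused", {
  tt <- tiny_trained()
  cfg <- slicenet_config(c(16, 16, 16), conv_filters = c(2, 2, 2, 2),
                         max_epochs = 1)
  expect_error(slicenet(tt$volumes[1:4], c(1, 1, 1, 1), cfg),
               "single class")
})

test_that("with no group effect the classifier stays near chance", {
  atl <- tiny_atlas()
  cc <- cohort_config(c(16, 16, 16), 24, prevalence = 0.5,
                      hypo_regions = 1, hyper_regions = 2,
                      effect_size = 0, noise_sd = 0.05, seed = 19)
  coh <- generate_cohort(cc, atl)
  nv <- lapply(coh$volumes, normalize_by_reference, atlas = atl)
  cfg <- slicenet_config(c(16, 16, 16), conv_filters = c(4, 4, 8, 8),
                         learning_rate = 1e-3, max_epochs = 2, seed = 3)
  fit <- slicenet(nv, coh$meta$label, cfg)
  # fresh null cohort as held-out data
  cc2 <- cc; cc2$seed <- 20L
  coh2 <- generate_cohort(cc2, atl)
  nv2 <- lapply(coh2$volumes, normalize_by_reference, atlas = atl)
  pr <- predict(fit, nv2)
  auc <- auc_score(pr$probability, coh2$meta$label)
  # n = 24 held-out subjects: AUC sampling SD is ~0.12 under the null
  expect_gt(auc, 0.15)
  expect_lt(auc, 0.85)
})
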