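test_that("the printed external operating point reproduces its accuracy", {
  # 50/50 split, sensitivity 0.80 and specificity 0.74 imply
  # TP = 40, FN = 10, TN = 37, FP = 13
  labels <- rep(c(1, 0), each = 50)
  predicted <- c(rep(1, 40), rep(0, 10), rep(1, 13), rep(0, 37))
  m <- compute_metrics(labels, predicted)
  expect_equal(unname(m$confusion),
               c(40L, 13L, 37L, 10L))  # TP FP TN FN
  expect_equal(m$accuracy, 0.770)
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$specificity, 0.74)
  expect_equal(m$f1, 2 * 40 / (2 * 40 + 13 + 10))
})

test_that("F1 by the 2TP formula equals the precision/recall harmonic mean", {
  set.seed(31)
  for (i in 1:30) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    predicted <- rbinom(n, 1, 0.5)
    cm <- confusion_matrix(predicted, labels)
    if (cm["TP"] == 0) next  # harmonic mean undefined
    prec <- cm["TP"] / (cm["TP"] + cm["FP"])
    rec <- cm["TP"] / (cm["TP"] + cm["FN"])
    m <- compute_metrics(labels, predicted)
    expect_equal(m$f1, unname(2 * prec * rec / (prec + rec)))
  }
})

test_that("AUC equals the all-pairs concordance oracle and pROC", {
  set.seed(32)
  for (i in 1:10) {
    n <- 50
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    a <- auc_score(p, labels)
    # oracle: fraction of concordant positive/negative pairs, ties = 1/2
    pos <- p[labels == 1]; neg <- p[labels == 0]
    conc <- 0
    for (x in pos) for (y in neg)
      conc <- conc + (x > y) + 0.5 * (x == y)
    expect_equal(a, conc / (length(pos) * length(neg)))
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(
      labels, p, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  }
  # invariance under a strictly monotone transform
  labels <- rep(c(1, 0), 25)
  p <- runif(50)
  expect_equal(auc_score(qlogis(p), labels), auc_score(p, labels))
  # perfect separation
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
})

test_that("single-class labels give NA AUC with a warning, other metrics stay", {
  expect_warning(a <- auc_score(runif(5), rep(1, 5)), "one class")
  expect_true(is.na(a))
  m <- suppressWarnings(compute_metrics(rep(1, 5), rep(1, 5),
                                        probabilities = runif(5)))
  expect_true(is.na(m$auc))
  expect_equal(m$accuracy, 1)
})

test_that("subgroup confusion matrices partition the overall one", {
  set.seed(33)
  n <- 60
  labels <- rbinom(n, 1, 0.5)
  predicted <- rbinom(n, 1, 0.5)
  subgroups <- sample(c("CU", "MCI", "dementia"), n, replace = TRUE)
  rep_df <- subgroup_report(labels, predicted, subgroups = subgroups)
  expect_equal(rep_df$subgroup[1], "overall")
  expect_equal(sum(rep_df$n[-1]), rep_df$n[1])
  cms <- lapply(unique(subgroups), function(g)
    confusion_matrix(predicted[subgroups == g], labels[subgroups == g]))
  expect_equal(Reduce(`+`, cms), confusion_matrix(predicted, labels))

  # a size-1 subgroup keeps defined metrics, AUC NA
  rep1 <- subgroup_report(c(1, 0, 0), c(1, 0, 1), c(0.9, 0.1, 0.6),
                          subgroups = c("CU", "MCI", "MCI"))
  cu <- rep1[rep1$subgroup == "CU", ]
  expect_equal(cu$accuracy, 1)
  expect_true(is.na(cu$auc))
})

test_that("the repeated protocol summarizes, orders its CI, and picks the best", {
  atl <- tiny_atlas()
  cc <- cohort_config(c(16, 16, 16), 40, hypo_regions = 1,
                      hyper_regions = 2, effect_size = 0.2,
                      noise_sd = 0.05, seed = 41)
  coh <- generate_cohort(cc, atl)
  nv <- lapply(coh$volumes, normalize_by_reference, atlas = atl)
  ext_cc <- cc; ext_cc$seed <- 42L; ext_cc$n_subjects <- 20L
  ext <- generate_cohort(ext_cc, atl)
  ext_nv <- lapply(ext$volumes, normalize_by_reference, atlas = atl)

  rp <- repeated_protocol(nv, coh$meta$label,
                          engine = roi_logistic_engine(atl),
                          n_repeats = 5,
                          external = list(volumes = ext_nv,
                                          labels = ext$meta$label),
                          seed = 7)
  expect_equal(nrow(rp$internal), 5L)
  expect_equal(nrow(rp$external), 5L)
  s <- rp$summary
  ok <- !is.na(s$lower)
  expect_true(all(s$lower[ok] <= s$mean[ok] + 1e-12))
  expect_true(all(s$mean[ok] <= s$upper[ok] + 1e-12))
  expect_equal(rp$best$rep, which.max(rp$internal$auc))
  expect_equal(rp$best$external$auc,
               rp$external$auc[rp$external$rep == rp$best$rep])

  # a mean within the CI of a longer rerun of the same protocol
  rp2 <- repeated_protocol(nv, coh$meta$label,
                           engine = roi_logistic_engine(atl),
                           n_repeats = 20, seed = 7)
  m5 <- rp$summary[rp$summary$metric == "auc" &
                     rp$summary$set == "internal", ]
  m20 <- rp2$summary[rp2$summary$metric == "auc" &
                       rp2$summary$set == "internal", ]
  expect_lt(abs(m5$mean - m20$mean), 0.25)
})

test_that("degenerate repetitions give zero-width intervals, one rep gives none", {
  vols <- lapply(1:20, function(i) array(i %% 2, c(2, 2, 2)))
  labels <- rep(c(1, 0), 10)
  # an engine that is already perfect and ignores training
  perfect <- function(volumes, labels, seed)
    function(new_volumes) vapply(new_volumes, function(v) v[1], numeric(1))
  rp <- repeated_protocol(vols, labels, perfect, n_repeats = 4, seed = 1)
  s <- rp$summary[rp$summary$metric == "auc", ]
  expect_equal(s$mean, 1)
  expect_equal(s$upper - s$lower, 0)

  expect_warning(r1 <- repeated_protocol(vols, labels, perfect,
                                         n_repeats = 1, seed = 1),
                 "unavailable")
  expect_true(all(is.na(r1$summary$lower)))
})

test_that("bootstrap CIs are available and ordered", {
  vols <- lapply(1:16, function(i) array(rnorm(8, i %% 2), c(2, 2, 2)))
  labels <- rep(c(1, 0), 8)
  eng <- function(volumes, labels, seed)
    function(nv) vapply(nv, mean, numeric(1))
  rp <- repeated_protocol(vols, labels, eng, n_repeats = 5, seed = 3,
                          ci = "bootstrap")
  s <- rp$summary
  ok <- !is.na(s$lower)
  expect_true(all(s$lower[ok] <= s$upper[ok]))
})
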