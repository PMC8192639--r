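#' Confusion matrix counts
#'
#' @param predicted,labels Binary vectors.
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(predicted, labels) {
  predicted <- as.integer(predicted)
  labels <- as.integer(labels)
  stopifnot(length(predicted) == length(labels))
  c(TP = sum(predicted == 1L & labels == 1L),
    FP = sum(predicted == 1L & labels == 0L),
    TN = sum(predicted == 0L & labels == 0L),
    FN = sum(predicted == 0L & labels == 1L))
}

#' Area under the ROC curve (midrank convention)
#'
#' Rank-based AUC equal to the fraction of concordant positive/negative
#' probability pairs, ties counting one half. Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param probabilities Numeric scores.
#' @param labels Binary vector.
#' @return AUC in `[0, 1]`, or `NA` (with a warning) when only one class
#'   is present.
#' @export
auc_score <- function(probabilities, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(probabilities)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics
#'
#' Accuracy, sensitivity, specificity, F1 and (when scores are supplied)
#' AUC. The F1 score follows the definition
#' `2 TP / (2 TP + FP + FN)`, which equals the harmonic mean of
#' precision and sensitivity whenever both are defined.
#'
#' @param labels Binary ground-truth vector.
#' @param predicted Binary predictions; derived from `probabilities` and
#'   `threshold` (strict `>`) when omitted.
#' @param probabilities Optional scores for the AUC.
#' @param threshold Decision threshold (default 0.5).
#' @param subgroup Optional tag carried into the output.
#' @return An `eval_metrics` list: `auc`, `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `n`, `confusion`, `subgroup`.
#' @examples
#' # printed external best-model operating point: 50/50 split,
#' # sens 0.80, spec 0.74 -> TP 40, FN 10, TN 37, FP 13 -> accuracy 0.770
#' m <- compute_metrics(labels = rep(c(1, 0), each = 50),
#'                      predicted = c(rep(1, 40), rep(0, 10),
#'                                    rep(1, 13), rep(0, 37)))
#' m$accuracy
#' @export
compute_metrics <- function(labels, predicted = NULL,
                            probabilities = NULL, threshold = 0.5,
                            subgroup = NULL) {
  labels <- as.integer(labels)
  if (is.null(predicted)) {
    if (is.null(probabilities))
      stop("either predicted classes or probabilities are required")
    predicted <- as.integer(probabilities > threshold)
  }
  cm <- confusion_matrix(predicted, labels)
  tp <- cm["TP"]; fp <- cm["FP"]; tn <- cm["TN"]; fn <- cm["FN"]
  n <- sum(cm)
  auc <- if (!is.null(probabilities) &&
             length(unique(labels)) == 2)
    auc_score(probabilities, labels) else NA_real_
  out <- list(
    auc = auc,
    accuracy = unname((tp + tn) / n),
    sensitivity = unname(if (tp + fn > 0) tp / (tp + fn) else NA_real_),
    specificity = unname(if (tn + fp > 0) tn / (tn + fp) else NA_real_),
    f1 = unname(if (2 * tp + fp + fn > 0)
      2 * tp / (2 * tp + fp + fn) else NA_real_),
    n = unname(n), confusion = cm, subgroup = subgroup
  )
  class(out) <- "eval_metrics"
  out
}

#' @export
print.eval_metrics <- function(x, digits = 3, ...) {
  if (!is.null(x$subgroup)) cat("subgroup:", x$subgroup, "\n")
  v <- c(AUC = x$auc, accuracy = x$accuracy, sensitivity = x$sensitivity,
         specificity = x$specificity, F1 = x$f1)
  print(round(v, digits))
  cat("n =", x$n, "\n")
  invisible(x)
}

#' Per-subgroup metric report
#'
#' One metrics row per diagnosis subgroup plus the overall row.
#' Subgroups containing a single class report the defined metrics and
#' `NA` for the rest (e.g. AUC).
#'
#' @param labels,predicted,probabilities As in [compute_metrics()].
#' @param subgroups Character tags covering all subjects.
#' @return Data frame with columns `subgroup`, `n`, `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
subgroup_report <- function(labels, predicted, probabilities = NULL,
                            subgroups) {
  stopifnot(length(subgroups) == length(labels))
  groups <- c(list(overall = rep(TRUE, length(labels))),
              lapply(setNames(nm = sort(unique(subgroups))),
                     function(g) subgroups == g))
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    m <- suppressWarnings(compute_metrics(
      labels[sel], predicted[sel],
      if (!is.null(probabilities)) probabilities[sel], subgroup = g))
    data.frame(subgroup = g, n = m$n, auc = m$auc, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               f1 = m$f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Repeated random-split evaluation protocol
#'
#' Repeats, `n_repeats` times: a fresh stratified train/validation split
#' (80/20 by default), a model fit on the training part, and evaluation
#' on the held-out part and (optionally) on a fixed external set. The
#' summary reports the mean of each metric with a 95\% confidence
#' interval across repetitions — normal approximation
#' `mean +/- 1.96 * SD / sqrt(R)` by default, or a percentile bootstrap —
#' and the external metrics of the single repetition with the best
#' internal AUC.
#'
#' @param volumes,labels The development cohort.
#' @param engine A fitting engine: `function(volumes, labels, seed)`
#'   returning a `function(volumes)` that yields probabilities. See
#'   [slicenet_engine()] and [roi_logistic_engine()].
#' @param n_repeats Number of repetitions (50 in the reference
#'   protocol).
#' @param train_frac Training fraction per split.
#' @param external Optional `list(volumes, labels)` evaluated by every
#'   repetition's model.
#' @param seed Base seed; repetition `r` uses `seed + r`.
#' @param ci `"normal"` or `"bootstrap"`.
#' @param threshold Decision threshold for class assignment.
#' @return A `repeated_eval`: `internal`/`external` per-repetition
#'   metric data frames, `summary` (mean, lower, upper per metric),
#'   `best` (repetition index plus its internal and external metrics).
#' @export
repeated_protocol <- function(volumes, labels, engine, n_repeats = 50L,
                              train_frac = 0.8, external = NULL,
                              seed = 1L, ci = c("normal", "bootstrap"),
                              threshold = 0.5) {
  ci <- match.arg(ci)
  labels <- as.integer(labels)
  if (n_repeats < 2)
    warning("n_repeats < 2: confidence intervals unavailable")
  internal <- list()
  external_rows <- list()
  for (r in seq_len(n_repeats)) {
    set.seed(seed + r)
    sp <- split_stratified(labels, train_frac)
    fit <- engine(volumes[sp$train], labels[sp$train], seed + r)
    p_int <- fit(volumes[sp$test])
    m <- suppressWarnings(compute_metrics(labels[sp$test],
                                          probabilities = p_int,
                                          threshold = threshold))
    internal[[r]] <- data.frame(rep = r, auc = m$auc,
                                accuracy = m$accuracy,
                                sensitivity = m$sensitivity,
                                specificity = m$specificity, f1 = m$f1)
    if (!is.null(external)) {
      p_ext <- fit(external$volumes)
      me <- suppressWarnings(compute_metrics(external$labels,
                                             probabilities = p_ext,
                                             threshold = threshold))
      external_rows[[r]] <- data.frame(rep = r, auc = me$auc,
                                       accuracy = me$accuracy,
                                       sensitivity = me$sensitivity,
                                       specificity = me$specificity,
                                       f1 = me$f1)
    }
  }
  internal <- do.call(rbind, internal)
  external_df <- if (length(external_rows)) do.call(rbind, external_rows)

  summarize <- function(df, which) {
    mets <- c("auc", "accuracy", "sensitivity", "specificity", "f1")
    do.call(rbind, lapply(mets, function(mn) {
      x <- df[[mn]]
      mu <- mean(x, na.rm = TRUE)
      if (n_repeats < 2) {
        lo <- hi <- NA_real_
      } else if (ci == "normal") {
        se <- sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
        lo <- mu - 1.96 * se; hi <- mu + 1.96 * se
      } else {
        bs <- replicate(2000, mean(sample(x, replace = TRUE),
                                   na.rm = TRUE))
        q <- quantile(bs, c(0.025, 0.975), na.rm = TRUE)
        lo <- q[1]; hi <- q[2]
      }
      data.frame(set = which, metric = mn, mean = mu, lower = lo,
                 upper = hi, stringsAsFactors = FALSE)
    }))
  }
  summ <- summarize(internal, "internal")
  if (!is.null(external_df))
    summ <- rbind(summ, summarize(external_df, "external"))
  rownames(summ) <- NULL

  best_rep <- if (all(is.na(internal$auc))) NA_integer_ else
    which.max(internal$auc)
  best <- list(rep = best_rep,
               internal = if (!is.na(best_rep))
                 internal[best_rep, ],
               external = if (!is.null(external_df) && !is.na(best_rep))
                 external_df[best_rep, ])

  structure(list(internal = internal, external = external_df,
                 summary = summ, best = best, n_repeats = n_repeats,
                 ci = ci),
            class = "repeated_eval")
}

#' @export
print.repeated_eval <- function(x, digits = 3, ...) {
  cat("repeated_eval: ", x$n_repeats, " repetitions (",
      x$ci, " 95% CI)\n", sep = "")
  s <- x$summary
  s[, c("mean", "lower", "upper")] <-
    round(s[, c("mean", "lower", "upper")], digits)
  print(s)
  if (!is.null(x$best$rep) && !is.na(x$best$rep))
    cat("best internal AUC at repetition", x$best$rep, "\n")
  invisible(x)
}

#' Fitting engines for the repeated protocol
#'
#' `slicenet_engine` wraps the 2.5-D network; `roi_logistic_engine` is a
#' fast baseline — logistic regression on atlas-region mean intensities —
#' useful for protocol-level experiments where retraining the network
#' every repetition is unnecessary.
#'
#' @param config A [slicenet_config()]; its seed is replaced by the
#'   per-repetition seed.
#' @return A function `(volumes, labels, seed)` returning a
#'   `function(volumes)` of probabilities.
#' @export
slicenet_engine <- function(config) {
  force(config)
  function(volumes, labels, seed) {
    cfg <- config
    cfg$seed <- as.integer(seed)
    fit <- slicenet(volumes, labels, cfg)
    function(new_volumes) predict(fit, new_volumes)$probability
  }
}

#' @rdname slicenet_engine
#' @param atlas A `pet_atlas` supplying the feature regions.
#' @export
roi_logistic_engine <- function(atlas) {
  force(atlas)
  ids <- atlas$regions$id[!atlas$regions$is_reference]
  masks <- lapply(ids, function(id) atlas$labels == id)
  featurize <- function(volumes) {
    t(vapply(volumes,
             function(v) vapply(masks, function(m) mean(v[m]), numeric(1)),
             numeric(length(masks))))
  }
  function(volumes, labels, seed) {
    X <- featurize(volumes)
    df <- as.data.frame(X)
    df$y <- labels
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    function(new_volumes) {
      nd <- as.data.frame(featurize(new_volumes))
      as.numeric(predict(fit, newdata = nd, type = "response"))
    }
  }
}
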