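#' Configuration for a 2.5-D slice-submodule network
#'
#' Defaults follow the published training recipe: four convolutional
#' layers of 32/64/128/128 filters (3x3 kernels, stride 1, same padding),
#' each followed by batch normalization, ReLU and 2x2 max pooling with
#' stride 2; per-slice sigmoid outputs fused by one fully connected
#' sigmoid unit; binary cross-entropy trained with Adam at learning rate
#' 1e-4, mini-batches of 4, at most 30 epochs, keeping the weights of the
#' epoch with the lowest internal-validation loss; decision threshold 0.5
#' (strict). For desk-scale experiments pass smaller `conv_filters`,
#' fewer epochs and a larger learning rate.
#'
#' @param dims Volume dimensions `(nx, ny, nz)`; slice counts and shapes
#'   derive from them. Every in-plane slice dimension must be `>= 16` so
#'   the feature map survives four halvings.
#' @param conv_filters Four filter counts.
#' @param learning_rate,batch_size,max_epochs,decision_threshold,
#'   val_fraction,bn_momentum,seed Training hyperparameters.
#' @return A `slicenet_config`.
#' @export
slicenet_config <- function(dims,
                            conv_filters = c(32L, 64L, 128L, 128L),
                            learning_rate = 1e-4,
                            batch_size = 4L,
                            max_epochs = 30L,
                            decision_threshold = 0.5,
                            val_fraction = 0.2,
                            bn_momentum = 0.1,
                            seed = 1L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  if (length(conv_filters) != 4)
    stop("conv_filters must have length 4")
  if (any(dims < 16))
    stop("every volume dimension must be >= 16 (dimension ",
         min(dims), " cannot survive four 2x2 poolings)")
  structure(list(
    dims = dims,
    slice_counts = c(sagittal = dims[1], coronal = dims[2],
                     axial = dims[3]),
    conv_filters = as.integer(conv_filters),
    kernel = 3L, conv_stride = 1L, pool = 2L, pool_stride = 2L,
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs),
    decision_threshold = decision_threshold,
    val_fraction = val_fraction, bn_momentum = bn_momentum,
    seed = as.integer(seed)
  ), class = "slicenet_config")
}

# per-axis slice shape (rows x cols of the plane fed to the submodule)
slice_shape_for_axis <- function(dims, axis) {
  switch(axis,
    sagittal = dims[2:3],   # ny x nz
    coronal  = dims[c(1, 3)],  # nx x nz
    axial    = dims[1:2])   # nx x ny
}

#' Build one 2-D submodule specification
#'
#' Initializes the parameters of a single per-slice submodule (four conv
#' + BN + ReLU + pool stages, then a fully connected sigmoid unit) for a
#' given slice shape, and reports its derived geometry: the pooled
#' feature-map shape, the flattened feature length, and the trainable
#' parameter count. Two submodules with equal slice shapes have equal
#' parameter counts; shapes only ever differ in the final fully connected
#' layer, because convolutions are shape-agnostic.
#'
#' @param slice_shape Integer `(rows, cols)` of the input plane, both
#'   `>= 16`.
#' @param config A [slicenet_config()] (only `conv_filters` is used).
#' @return A `slicenet_submodule` with elements `par`, `bn`, `shape`,
#'   `filters`, `feat_shape`, `feat_len`, `n_params`.
#' @examples
#' cfg <- slicenet_config(c(32, 32, 32))
#' sub <- build_submodule(c(32, 32), cfg)
#' sub$feat_len  # 2 * 2 * 128 = 512
#' @export
build_submodule <- function(slice_shape, config) {
  sub <- init_submodule_params(as.integer(slice_shape),
                               config$conv_filters)
  sub$n_params <- sum(vapply(sub$par, length, integer(1)))
  class(sub) <- "slicenet_submodule"
  sub
}

#' @export
print.slicenet_submodule <- function(x, ...) {
  cat("slicenet_submodule: input ", paste(x$shape, collapse = " x "),
      ", filters ", paste(x$filters, collapse = "/"),
      ", pooled map ", paste(x$feat_shape, collapse = " x "),
      ", ", format(x$n_params, big.mark = ","), " trainable parameters\n",
      sep = "")
  invisible(x)
}

#' Build an untrained 2.5-D model
#'
#' Instantiates `nx + ny + nz` independent (non-weight-shared) submodules
#' — one per sagittal, coronal and axial slice — plus the fully connected
#' sigmoid head that fuses their per-slice predictions. Parameters are
#' freshly initialized (He for convolutions, Xavier for the fully
#' connected units) under the config seed.
#'
#' @param config A [slicenet_config()].
#' @return A `slicenet` object with `trained = FALSE`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "slicenet_config"))
  set.seed(config$seed)
  axes <- rep(c("sagittal", "coronal", "axial"), config$slice_counts)
  index <- unlist(lapply(config$slice_counts, seq_len), use.names = FALSE)
  S <- length(axes)
  subs <- vector("list", S)
  for (s in seq_len(S)) {
    shp <- slice_shape_for_axis(config$dims, axes[s])
    subs[[s]] <- build_submodule(shp, config)
  }
  head_par <- list(w = xavier_init(S, S, 1L), b = 0)
  structure(list(
    config = config, submodules = subs, head = head_par,
    axis = axes, index = index, n_submodules = S,
    trained = FALSE, history = NULL, checkpoint_epoch = NA_integer_
  ), class = "slicenet")
}

# forward pass of the whole model in evaluation mode (running BN stats)
# volumes: list of arrays; ids: indices. Returns list(P = S x n submodule
# probabilities, f = final probabilities).
forward_model_eval <- function(model, volumes, ids) {
  S <- model$n_submodules
  n <- length(ids)
  P <- matrix(0, S, n)
  for (s in seq_len(S)) {
    X <- slice_batch(volumes, ids, model$axis[s], model$index[s])
    P[s, ] <- forward_sub(model$submodules[[s]], X, n,
                          training = FALSE)$s
  }
  f <- sigmoid(colSums(P * model$head$w) + model$head$b)
  list(P = P, f = f)
}

#' Fit a 2.5-D slice-submodule network
#'
#' Trains the full architecture end-to-end with binary cross-entropy on
#' the final sigmoid output. Subjects are split into training and
#' internal-validation sets by a stratified random split; validation loss
#' is recorded after every epoch and the returned weights are those of
#' the epoch with the lowest validation loss. Training is deterministic
#' for a fixed config seed on one machine.
#'
#' @param volumes List of 3-D arrays, all with the config's dimensions.
#' @param labels Binary vector (0/1), one per volume; both classes must
#'   be present.
#' @param config A [slicenet_config()].
#' @param subject_ids Optional identifiers (defaults to `V0001`, ...).
#' @param verbose Print per-epoch losses.
#' @return A fitted `slicenet` with `history` (per-epoch training and
#'   validation loss), `checkpoint_epoch`, and `val_idx` (the internal
#'   validation subjects).
#' @seealso [predict.slicenet()], [interpret_slicenet()]
#' @export
slicenet <- function(volumes, labels, config, subject_ids = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(config, "slicenet_config"))
  labels <- as.integer(labels)
  n <- length(volumes)
  if (n != length(labels)) stop("volumes and labels lengths differ")
  if (length(unique(labels)) < 2)
    stop("training data contain a single class; both classes are required")
  for (v in volumes)
    if (!all(dim(v) == config$dims))
      stop("a volume's dims (", paste(dim(v), collapse = ", "),
           ") do not match the config dims")
  subject_ids <- subject_ids %||% sprintf("V%04d", seq_len(n))

  set.seed(config$seed)
  model <- build_model_noseed(config)
  sp <- split_stratified(labels, 1 - config$val_fraction)
  train_idx <- sp$train
  val_idx <- sp$test
  if (length(unique(labels[train_idx])) < 2)
    stop("training split contains a single class")

  S <- model$n_submodules
  states <- lapply(model$submodules, function(s) adam_state(s$par))
  head_state <- adam_state(model$head)
  lr <- config$learning_rate
  bs <- config$batch_size
  tstep <- 0L
  hist_tr <- numeric(0)
  hist_va <- numeric(0)
  best_loss <- Inf
  best <- NULL

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(train_idx)
    ep_loss <- 0
    ep_n <- 0L
    for (b0 in seq(1, length(ord), by = bs)) {
      ids <- ord[b0:min(b0 + bs - 1L, length(ord))]
      N <- length(ids)
      y <- labels[ids]
      P <- matrix(0, S, N)
      caches <- vector("list", S)
      for (s in seq_len(S)) {
        X <- slice_batch(volumes, ids, model$axis[s], model$index[s])
        fw <- forward_sub(model$submodules[[s]], X, N, training = TRUE,
                          bn_momentum = config$bn_momentum)
        P[s, ] <- fw$s
        caches[[s]] <- fw$cache
        model$submodules[[s]]$bn <- fw$bn
      }
      f <- sigmoid(colSums(P * model$head$w) + model$head$b)
      loss <- bce_loss(f, y)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; aborting (check inputs and learning rate)")
      ep_loss <- ep_loss + loss * N
      ep_n <- ep_n + N
      tstep <- tstep + 1L

      dv <- (f - y) / N
      hg <- list(w = as.vector(P %*% dv), b = sum(dv))
      dP <- outer(model$head$w, dv)
      for (s in seq_len(S)) {
        g <- backward_sub(model$submodules[[s]], caches[[s]], dP[s, ], N)
        g$dX <- NULL
        up <- adam_step(model$submodules[[s]]$par, g, states[[s]], lr,
                        tstep)
        model$submodules[[s]]$par <- up$par
        states[[s]] <- up$state
      }
      up <- adam_step(model$head, hg, head_state, lr, tstep)
      model$head <- up$par
      head_state <- up$state
    }
    tr_loss <- ep_loss / ep_n

    va <- forward_model_eval(model, volumes, val_idx)
    va_loss <- bce_loss(va$f, labels[val_idx])
    hist_tr <- c(hist_tr, tr_loss)
    hist_va <- c(hist_va, va_loss)
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %.4f", epoch, tr_loss,
                      va_loss))
    if (va_loss < best_loss) {
      best_loss <- va_loss
      best <- list(
        sub_par = lapply(model$submodules, `[[`, "par"),
        sub_bn = lapply(model$submodules, `[[`, "bn"),
        head = model$head, epoch = epoch
      )
    }
  }

  # restore the lowest-validation-loss checkpoint
  for (s in seq_len(S)) {
    model$submodules[[s]]$par <- best$sub_par[[s]]
    model$submodules[[s]]$bn <- best$sub_bn[[s]]
  }
  model$head <- best$head
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_along(hist_tr),
                              train_loss = hist_tr, val_loss = hist_va)
  model$checkpoint_epoch <- best$epoch
  model$train_idx <- train_idx
  model$val_idx <- val_idx
  model$subject_ids <- subject_ids
  model$labels <- labels
  model$call <- match.call()
  model
}

# build_model without touching the RNG (slicenet controls the seed once)
build_model_noseed <- function(config) {
  axes <- rep(c("sagittal", "coronal", "axial"), config$slice_counts)
  index <- unlist(lapply(config$slice_counts, seq_len), use.names = FALSE)
  S <- length(axes)
  subs <- vector("list", S)
  for (s in seq_len(S)) {
    shp <- slice_shape_for_axis(config$dims, axes[s])
    subs[[s]] <- build_submodule(shp, config)
  }
  head_par <- list(w = xavier_init(S, S, 1L), b = 0)
  structure(list(
    config = config, submodules = subs, head = head_par,
    axis = axes, index = index, n_submodules = S,
    trained = FALSE, history = NULL, checkpoint_epoch = NA_integer_
  ), class = "slicenet")
}

#' Predict amyloid status for new volumes
#'
#' Runs the fitted network in evaluation mode (batch normalization uses
#' running moments, so inference is deterministic) and returns, per
#' subject, the final probability, the thresholded class (positive only
#' when strictly above the decision threshold), and the full vector of
#' per-submodule probabilities needed by the interpretation stage.
#'
#' @param object A fitted `slicenet`.
#' @param volumes List of 3-D arrays matching the training dimensions.
#' @param subject_ids Optional identifiers.
#' @param batch_size Subjects per forward chunk.
#' @param ... Unused.
#' @return A `slicenet_predictions` data frame (`subject_id`,
#'   `probability`, `class`) whose attributes carry the `S x n` submodule
#'   probability matrix (`submodule_probabilities`) and the slice
#'   axis/index map.
#' @export
predict.slicenet <- function(object, volumes, subject_ids = NULL,
                             batch_size = 8L, ...) {
  if (!is.list(volumes)) volumes <- list(volumes)
  for (v in volumes)
    if (!all(dim(v) == object$config$dims))
      stop("volume dims (", paste(dim(v), collapse = ", "),
           ") do not match the model dims (",
           paste(object$config$dims, collapse = ", "), ")")
  n <- length(volumes)
  subject_ids <- subject_ids %||% sprintf("V%04d", seq_len(n))
  S <- object$n_submodules
  P <- matrix(0, S, n)
  f <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1L, n)
    fw <- forward_model_eval(object, volumes, ids)
    P[, ids] <- fw$P
    f[ids] <- fw$f
  }
  out <- data.frame(subject_id = subject_ids, probability = f,
                    class = as.integer(f > object$config$decision_threshold),
                    stringsAsFactors = FALSE)
  attr(out, "submodule_probabilities") <- P
  attr(out, "axis") <- object$axis
  attr(out, "index") <- object$index
  attr(out, "threshold") <- object$config$decision_threshold
  class(out) <- c("slicenet_predictions", "data.frame")
  out
}

#' @export
print.slicenet <- function(x, ...) {
  cat("slicenet 2.5-D model\n")
  cat("  volume dims: ", paste(x$config$dims, collapse = " x "), "\n",
      sep = "")
  cat("  submodules:  ", x$n_submodules, " (",
      paste(x$config$slice_counts, collapse = " + "), ")\n", sep = "")
  cat("  filters:     ", paste(x$config$conv_filters, collapse = "/"),
      "\n", sep = "")
  if (x$trained) {
    cat("  trained:     ", nrow(x$history), " epochs, checkpoint at epoch ",
        x$checkpoint_epoch, " (val loss ",
        signif(x$history$val_loss[x$checkpoint_epoch], 4), ")\n", sep = "")
  } else cat("  trained:     no\n")
  invisible(x)
}

#' @export
summary.slicenet <- function(object, ...) {
  n_par <- sum(vapply(object$submodules, `[[`, numeric(1), "n_params")) +
    length(object$head$w) + 1
  out <- list(
    dims = object$config$dims,
    n_submodules = object$n_submodules,
    slice_counts = object$config$slice_counts,
    conv_filters = object$config$conv_filters,
    n_parameters = n_par,
    trained = object$trained,
    checkpoint_epoch = object$checkpoint_epoch,
    history = object$history
  )
  class(out) <- "summary.slicenet"
  out
}

#' @export
print.summary.slicenet <- function(x, ...) {
  cat("2.5-D slice-submodule network\n")
  cat("  ", x$n_submodules, " submodules (",
      paste(x$slice_counts, collapse = " + "), "), filters ",
      paste(x$conv_filters, collapse = "/"), "\n", sep = "")
  cat("  total trainable parameters: ",
      format(x$n_parameters, big.mark = ","), "\n", sep = "")
  if (x$trained) {
    cat("  checkpoint epoch: ", x$checkpoint_epoch, "\n", sep = "")
    print(head(x$history, 10))
  }
  invisible(x)
}

#' @export
coef.slicenet <- function(object, ...) {
  c(setNames(object$head$w, paste0(object$axis, "_", object$index)),
    bias = object$head$b)
}

#' Training-history plot
#'
#' @param x A fitted `slicenet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.slicenet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  graphics::matplot(x$history$epoch,
                    cbind(x$history$train_loss, x$history$val_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "binary cross-entropy", ...)
  graphics::abline(v = x$checkpoint_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   lty = 1, col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
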