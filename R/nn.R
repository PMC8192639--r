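# Internal layer plumbing for the per-slice submodules.
#
# A submodule is 4 x [conv 3x3 stride 1, same padding -> batch norm ->
# ReLU -> 2x2 max pool stride 2] followed by flatten -> fully connected
# unit -> sigmoid. Batched feature maps travel as 3-D arrays of dimension
# H x W x (C * N) (sample-major slices), matching the compiled kernels.
# Conv weights are He-initialized, the fully connected unit
# Xavier-initialized. Only pooling reduces resolution; with floor
# division an in-plane dimension must be >= 16 to survive four halvings.

BN_EPS <- 1e-5

he_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / nrow)), nrow, ncol)
}

xavier_init <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# spatial shape after the four pooling stages (floor division)
pooled_shape <- function(shape) {
  for (i in 1:4) shape <- shape %/% 2L
  shape
}

check_slice_shape <- function(shape) {
  bad <- which(shape < 16L)
  if (length(bad))
    stop("slice dimension ", shape[bad[1]], " cannot survive four 2x2 ",
         "poolings; every in-plane dimension must be >= 16")
}

init_submodule_params <- function(shape, filters) {
  check_slice_shape(shape)
  cin <- c(1L, filters[-4])
  par <- list()
  bn <- list()
  for (l in 1:4) {
    par[[paste0("W", l)]] <- he_init(9L * cin[l], filters[l])
    par[[paste0("b", l)]] <- numeric(filters[l])
    par[[paste0("g", l)]] <- rep(1, filters[l])
    par[[paste0("be", l)]] <- numeric(filters[l])
    bn[[paste0("rm", l)]] <- numeric(filters[l])
    bn[[paste0("rv", l)]] <- rep(1, filters[l])
  }
  fshape <- pooled_shape(shape)
  feat_len <- prod(fshape) * filters[4]
  par$Wf <- xavier_init(feat_len, feat_len, 1L)
  par$bf <- 0
  list(par = par, bn = bn, shape = as.integer(shape),
       filters = as.integer(filters),
       feat_shape = c(fshape, filters[4]), feat_len = feat_len)
}

# forward through one submodule on a batch of N single-channel slices
# X: array H x W x N. Returns sigmoid outputs and, in training mode, the
# cache needed for backprop plus updated running BN moments.
forward_sub <- function(sub, X, N, training = FALSE, bn_momentum = 0.1) {
  filters <- sub$filters
  A <- X
  cache <- if (training)
    list(A = vector("list", 4), Z = vector("list", 4),
         B = vector("list", 4), idx = vector("list", 4),
         stat = vector("list", 4), preHW = vector("list", 4))
  bn <- sub$bn
  for (l in 1:4) {
    Wl <- sub$par[[paste0("W", l)]]
    Z <- .conv_fwd(A, N, Wl, sub$par[[paste0("b", l)]])
    st <- .bn_fwd(Z, N, sub$par[[paste0("g", l)]],
                  sub$par[[paste0("be", l)]], BN_EPS, training,
                  bn[[paste0("rm", l)]], bn[[paste0("rv", l)]])
    B <- st$Y
    R <- B
    R[R < 0] <- 0
    pr <- .pool_fwd(R)
    if (training) {
      m <- N * dim(Z)[1] * dim(Z)[2]
      unb <- if (m > 1) m / (m - 1) else 1
      bn[[paste0("rm", l)]] <- (1 - bn_momentum) * bn[[paste0("rm", l)]] +
        bn_momentum * st$mean
      bn[[paste0("rv", l)]] <- (1 - bn_momentum) * bn[[paste0("rv", l)]] +
        bn_momentum * st$var * unb
      cache$A[[l]] <- A
      cache$Z[[l]] <- Z
      cache$B[[l]] <- B
      cache$idx[[l]] <- pr$idx
      cache$stat[[l]] <- st
      cache$preHW[[l]] <- dim(Z)[1:2]
    }
    A <- pr$Y
  }
  C4 <- filters[4]
  h <- dim(A)[1]; w <- dim(A)[2]
  feat <- matrix(0, h * w * C4, N)
  for (n in seq_len(N))
    feat[, n] <- A[, , (n - 1L) * C4 + seq_len(C4)]
  u <- colSums(feat * sub$par$Wf) + sub$par$bf
  s <- sigmoid(u)
  if (training) {
    cache$feat <- feat
    cache$u <- u
    cache$s <- s
    cache$out_hw <- c(h, w)
  }
  list(s = s, cache = cache, bn = bn)
}

# backward through one submodule; ds = dLoss/d(sigmoid output), length N.
# Returns gradients named like the trainable parameters.
backward_sub <- function(sub, cache, ds, N) {
  filters <- sub$filters
  du <- ds * cache$s * (1 - cache$s)
  grads <- list(
    Wf = as.vector(cache$feat %*% du),
    bf = sum(du)
  )
  dfeat <- outer(sub$par$Wf, du)
  C4 <- filters[4]
  h <- cache$out_hw[1]; w <- cache$out_hw[2]
  dA <- array(0, c(h, w, C4 * N))
  for (n in seq_len(N))
    dA[, , (n - 1L) * C4 + seq_len(C4)] <- dfeat[, n]
  for (l in 4:1) {
    hw <- cache$preHW[[l]]
    dR <- .pool_bwd(dA, cache$idx[[l]], hw[1], hw[2])
    dB <- dR * (cache$B[[l]] > 0)
    st <- cache$stat[[l]]
    bb <- .bn_bwd(dB, cache$Z[[l]], N, sub$par[[paste0("g", l)]],
                  st$mean, st$var, BN_EPS)
    cb <- .conv_bwd(cache$A[[l]], N, sub$par[[paste0("W", l)]], bb$dX)
    grads[[paste0("W", l)]] <- cb$dW
    grads[[paste0("b", l)]] <- as.vector(cb$db)
    grads[[paste0("g", l)]] <- as.vector(bb$dgamma)
    grads[[paste0("be", l)]] <- as.vector(bb$dbeta)
    dA <- cb$dX
  }
  grads$dX <- dA
  grads
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}

adam_step <- function(par, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(par = par, state = state)
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# gather the batch of slices feeding submodule (axis, index)
slice_batch <- function(volumes, ids, axis, index) {
  n <- length(ids)
  first <- switch(axis,
    sagittal = volumes[[ids[1]]][index, , , drop = TRUE],
    coronal  = volumes[[ids[1]]][, index, , drop = TRUE],
    axial    = volumes[[ids[1]]][, , index, drop = TRUE])
  X <- array(0, c(dim(first), n))
  X[, , 1] <- first
  if (n > 1) for (i in 2:n) {
    X[, , i] <- switch(axis,
      sagittal = volumes[[ids[i]]][index, , , drop = TRUE],
      coronal  = volumes[[ids[i]]][, index, , drop = TRUE],
      axial    = volumes[[ids[i]]][, , index, drop = TRUE])
  }
  X
}
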