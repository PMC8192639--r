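sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-width-at-half-maximum to Gaussian sigma
#'
#' Standard neuroimaging conversion, `sigma = fwhm / (2 * sqrt(2 * log(2)))`.
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Standard deviation of the equivalent Gaussian, same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Applies a 1-D Gaussian kernel along each axis in turn. The kernel is
#' truncated at three standard deviations and renormalized per position at
#' the volume edges, so constant volumes stay constant.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_vox Kernel full width at half maximum, in voxels. Values
#'   `<= 0` return the input unchanged.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_smooth_3d <- function(volume, fwhm_vox) {
  stopifnot(length(dim(volume)) == 3)
  if (fwhm_vox <= 0) return(volume)
  sigma <- fwhm_to_sigma(fwhm_vox)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)

  smooth_axis <- function(x, axis) {
    n <- dim(x)[axis]
    # banded kernel matrix with edge renormalization
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1L, i - r):min(n, i + r)
      w <- k[j - i + r + 1L]
      K[i, j] <- w / sum(w)
    }
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    m <- matrix(xp, nrow = n)
    res <- array(K %*% m, dim = d[perm])
    aperm(res, order(perm))
  }
  for (a in 1:3) volume <- smooth_axis(volume, a)
  volume
}

rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  (rowSums(x * x) - n * m * m) / (n - 1)
}

# stratified index split: returns list(train, test) preserving class balance
split_stratified <- function(labels, train_frac) {
  idx <- seq_along(labels)
  train <- integer(0)
  for (cl in unique(labels)) {
    cl_idx <- idx[labels == cl]
    n_tr <- round(train_frac * length(cl_idx))
    n_tr <- max(1L, min(length(cl_idx) - 1L, n_tr))
    train <- c(train, sample(cl_idx, n_tr))
  }
  list(train = sort(train), test = sort(setdiff(idx, train)))
}
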