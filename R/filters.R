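# Separable image filtering used by spot detection and focus projection.
# Convolution along one array axis is a matrix product with a banded kernel
# matrix, which keeps everything in BLAS and fully deterministic.

gauss_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n convolution matrix for kernel k (odd length), zero padding
conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  m <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    m[cbind(idx[ok], src[ok])] <- m[cbind(idx[ok], src[ok])] + k[j]
  }
  m
}

# convolve a 3D array along axis (1=y, 2=x, 3=z) with 1D kernel k
conv_axis3d <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr * k)
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- conv_matrix(da[1], k)
  out <- m %*% matrix(a, nrow = da[1])
  dim(out) <- da
  aperm(out, order(perm))
}

gaussian_blur3d <- function(arr, sigma_xy, sigma_z) {
  out <- conv_axis3d(arr, gauss_kernel(sigma_xy), 1L)
  out <- conv_axis3d(out, gauss_kernel(sigma_xy), 2L)
  conv_axis3d(out, gauss_kernel(sigma_z), 3L)
}

# convolve a matrix along rows/cols with 1D kernel (zero padding)
conv_axis2d <- function(mat, k, axis) {
  if (length(k) == 1L) return(mat * k)
  if (axis == 1L) conv_matrix(nrow(mat), k) %*% mat
  else mat %*% t(conv_matrix(ncol(mat), k))
}

# local variance in a w x w window (w odd), edge-corrected box means
local_variance <- function(mat, w) {
  stopifnot(w %% 2 == 1, w >= 3)
  box <- rep(1, w)
  s1 <- conv_axis2d(conv_axis2d(mat, box, 1L), box, 2L)
  s2 <- conv_axis2d(conv_axis2d(mat^2, box, 1L), box, 2L)
  ones <- matrix(1, nrow(mat), ncol(mat))
  n <- conv_axis2d(conv_axis2d(ones, box, 1L), box, 2L)
  v <- s2 / n - (s1 / n)^2
  pmax(v, 0)
}
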