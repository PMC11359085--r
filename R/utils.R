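# Internal numerical helpers shared across modules.

# Reshape an I x J x K cube array into a K x (I*J) matrix whose column p holds
# the time series of pixel p in column-major (i, j) order.
cube_to_matrix <- function(a) {
  d <- dim(a)
  matrix(aperm(a, c(3L, 1L, 2L)), nrow = d[3L])
}

# Inverse of cube_to_matrix.
matrix_to_cube <- function(m, I, J) {
  aperm(array(m, dim = c(nrow(m), I, J)), c(2L, 3L, 1L))
}

# Mirror-fold arbitrary (possibly out-of-range) positions into 1..n.
reflect_index <- function(p, n) {
  if (n == 1L) return(rep(1L, length(p)))
  period <- 2L * n - 2L
  q <- (p - 1L) %% period
  q <- ifelse(q >= n, period - q, q)
  q + 1L
}

# Reflective (mirror) padding of a matrix by (pr, pc) on each side; the
# padding may exceed the matrix size (the reflection folds repeatedly).
pad_reflect <- function(x, pr, pc) {
  ri <- reflect_index((1L - pr):(nrow(x) + pr), nrow(x))
  ci <- reflect_index((1L - pc):(ncol(x) + pc), ncol(x))
  x[ri, ci, drop = FALSE]
}

# 2-D convolution with reflective boundary handling. `k` must have odd sides.
conv2_reflect <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  if (kr %% 2L == 0L || kc %% 2L == 0L)
    stop("convolution kernel must have odd side lengths")
  if (kr == 1L && kc == 1L) return(x * k[1L, 1L])
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  xp <- pad_reflect(x, pr, pc)
  out <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(kr)) for (b in seq_len(kc)) {
    w <- k[a, b]
    if (w != 0)
      out <- out + w * xp[(a - 1L) + seq_len(nrow(x)), (b - 1L) + seq_len(ncol(x)), drop = FALSE]
  }
  out
}

# Convolve every frame of an I x J x K array with a kernel, reflective
# boundaries, vectorized over frames.
conv_cube_reflect <- function(a, k) {
  kr <- nrow(k); kc <- ncol(k)
  if (kr == 1L && kc == 1L) return(a * k[1L, 1L])
  pr <- (kr - 1L) %/% 2L; pc <- (kc - 1L) %/% 2L
  d <- dim(a)
  ri <- reflect_index((1L - pr):(d[1L] + pr), d[1L])
  ci <- reflect_index((1L - pc):(d[2L] + pc), d[2L])
  ap <- a[ri, ci, , drop = FALSE]
  out <- array(0, d)
  for (x in seq_len(kr)) for (y in seq_len(kc)) {
    w <- k[x, y]
    if (w != 0)
      out <- out + w * ap[(x - 1L) + seq_len(d[1L]),
                          (y - 1L) + seq_len(d[2L]), , drop = FALSE]
  }
  out
}

#' Gaussian blur kernel
#'
#' Builds a normalized, odd-sided 2-D Gaussian kernel with the side length
#' \code{2 * ceiling(3 * sigma) + 1}. A width of zero yields the 1x1 identity
#' kernel.
#'
#' @param sigma Kernel standard deviation in pixels (>= 0).
#' @return A square numeric matrix with non-negative entries summing to one.
#' @export
gaussian_kernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(matrix(1, 1L, 1L))
  h <- ceiling(3 * sigma)
  g <- exp(-((-h):h)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian-smooth a matrix of white noise and rescale to unit variance; used
# to build spatially correlated parameter jitter and fixed-pattern fields.
smooth_field <- function(x, sigma) {
  if (sigma <= 0) return(x)
  y <- conv2_reflect(x, gaussian_kernel(sigma))
  s <- stats::sd(as.vector(y))
  if (s == 0) return(y)
  y / s
}

# Column-wise Pearson correlation between two equal-shape matrices.
colwise_pearson <- function(a, b) {
  n <- nrow(a)
  ca <- sweep(a, 2L, colMeans(a))
  cb <- sweep(b, 2L, colMeans(b))
  sa <- sqrt(colSums(ca^2))
  sb <- sqrt(colSums(cb^2))
  num <- colSums(ca * cb)
  out <- num / (sa * sb)
  out[sa == 0 | sb == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
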