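# 2-D convolution with explicit boundary handling.
#
# Kernels are plain matrices carrying an optional "origin" attribute: the
# 1-based position of the zero-offset tap. Kernels with odd dimensions
# default to a centered origin (zero phase); others to the top-left tap.

kernel_origin <- function(k) {
  o <- attr(k, "origin")
  if (!is.null(o)) return(as.integer(o))
  d <- dim(k)
  as.integer(ifelse(d %% 2L == 1L, (d + 1L) %/% 2L, 1L))
}

# Reflected (half-sample symmetric) index lookup: ... 2 1 | 1 2 ... n n | n n-1 ...
reflect_idx <- function(i, n) {
  m <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n)
  ifelse(m < n, m + 1L, 2L * n - m)
}

# Circular convolution of x with taps w at integer offsets (dr, dc),
# via the DFT. Offsets wrap modulo the image size, so kernels larger
# than the image are handled correctly.
conv2_circular <- function(x, dr, dc, w) {
  nr <- nrow(x); nc <- ncol(x)
  K <- matrix(0, nr, nc)
  ir <- (dr %% nr) + 1L
  ic <- (dc %% nc) + 1L
  for (t in seq_along(w)) K[ir[t], ic[t]] <- K[ir[t], ic[t]] + w[t]
  Re(fft(fft(x) * fft(K), inverse = TRUE)) / (nr * nc)
}

#' Same-size 2-D convolution with selectable boundary extension
#'
#' Convolves an image with a kernel, returning an output of the input's
#' size. `"periodic"` wraps the image (exact for shift-invariance and
#' perfect-reconstruction arguments); `"symmetric"` mirror-extends it
#' (avoids wrap-around artifacts on natural images).
#'
#' @param x Numeric matrix.
#' @param k Kernel matrix; an optional `"origin"` attribute gives the
#'   1-based position of the zero-offset tap (defaults to the center for
#'   odd-sized kernels).
#' @param boundary `"symmetric"` or `"periodic"`.
#' @return Matrix of `dim(x)`.
#' @export
conv2_same <- function(x, k, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(x), is.matrix(k))
  o <- kernel_origin(k)
  nz <- which(k != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(matrix(0, nrow(x), ncol(x)))
  w <- k[nz]
  dr <- nz[, 1L] - o[1L]
  dc <- nz[, 2L] - o[2L]
  if (boundary == "periodic") {
    return(conv2_circular(x, dr, dc, w))
  }
  nr <- nrow(x); nc <- ncol(x)
  pr <- max(abs(dr)); pc <- max(abs(dc))
  ri <- reflect_idx((1L - pr):(nr + pr), nr)
  ci <- reflect_idx((1L - pc):(nc + pc), nc)
  xp <- x[ri, ci, drop = FALSE]
  yp <- conv2_circular(xp, dr, dc, w)
  yp[(pr + 1L):(pr + nr), (pc + 1L):(pc + nc), drop = FALSE]
}

# Shift an image by (dr, dc) with reflected boundary: y(i,j) = x(i+dr, j+dc).
translate_reflect <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  x[reflect_idx((1L + dr):(nr + dr), nr),
    reflect_idx((1L + dc):(nc + dc), nc), drop = FALSE]
}

# Full 2-D convolution of two (small) kernels; origins add.
conv2_kernels <- function(a, b) {
  oa <- kernel_origin(a); ob <- kernel_origin(b)
  ra <- nrow(a); ca <- ncol(a); rb <- nrow(b); cb <- ncol(b)
  out <- matrix(0, ra + rb - 1L, ca + cb - 1L)
  for (i in seq_len(rb)) {
    for (j in seq_len(cb)) {
      if (b[i, j] != 0)
        out[i:(i + ra - 1L), j:(j + ca - 1L)] <-
          out[i:(i + ra - 1L), j:(j + ca - 1L)] + a * b[i, j]
    }
  }
  attr(out, "origin") <- oa + ob - 1L
  out
}

# Linear combination of kernels on a common (centered) support.
kernel_lincomb <- function(kernels, coefs) {
  stopifnot(length(kernels) == length(coefs))
  reach_r <- 0L; reach_c <- 0L
  for (k in kernels) {
    o <- kernel_origin(k)
    reach_r <- max(reach_r, o[1L] - 1L, nrow(k) - o[1L])
    reach_c <- max(reach_c, o[2L] - 1L, ncol(k) - o[2L])
  }
  out <- matrix(0, 2L * reach_r + 1L, 2L * reach_c + 1L)
  oc <- c(reach_r + 1L, reach_c + 1L)
  for (i in seq_along(kernels)) {
    k <- kernels[[i]]
    if (coefs[i] == 0) next
    o <- kernel_origin(k)
    r0 <- oc[1L] - o[1L]; c0 <- oc[2L] - o[2L]
    out[(r0 + 1L):(r0 + nrow(k)), (c0 + 1L):(c0 + ncol(k))] <-
      out[(r0 + 1L):(r0 + nrow(k)), (c0 + 1L):(c0 + ncol(k))] + coefs[i] * k
  }
  attr(out, "origin") <- oc
  out
}

delta_kernel <- function() {
  k <- matrix(1, 1L, 1L)
  attr(k, "origin") <- c(1L, 1L)
  k
}

# Isotropic Gaussian kernel, truncated at ~3.5 sigma, normalized to unit sum.
gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3.5 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

gaussian_smooth <- function(x, sigma, boundary = "symmetric") {
  conv2_same(x, gaussian_kernel(sigma), boundary = boundary)
}
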