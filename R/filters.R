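# Two-channel nonsubsampled filter banks.
#
# A filter quad holds analysis kernels (h0 low, h1 high) and synthesis
# kernels (g0, g1) satisfying the Bezout identity
#     H0(z) G0(z) + H1(z) G1(z) = 1,
# which is exactly the perfect-reconstruction condition of an
# undecimated two-channel bank. Both families below satisfy it exactly
# in tap arithmetic, by construction:
#
#  * pyramid quads use the Laplacian structure h1 = delta - h0*g0, g1 = delta;
#  * fan quads use h0 = f, g0 = 2 delta - f, h1 = g1 = delta - f, where f is
#    a zero-phase fan filter with F(0,0) = 1/2, so that
#    F (2 - F) + (1 - F)^2 = 1 identically.

new_filter_quad <- function(h0, h1, g0, g1, name, kind) {
  structure(list(h0 = h0, h1 = h1, g0 = g0, g1 = g1,
                 name = name, kind = kind),
            class = "nss_filter_quad")
}

#' @export
print.nss_filter_quad <- function(x, ...) {
  cat(sprintf("<nss_filter_quad '%s' (%s): h0 %dx%d, h1 %dx%d>\n",
              x$name, x$kind, nrow(x$h0), ncol(x$h0), nrow(x$h1), ncol(x$h1)))
  invisible(x)
}

# CDF 9/7 biorthogonal lowpass taps (analysis / synthesis), normalized to
# unit DC gain.
cdf97_analysis_lp <- function() {
  a <- c(0.026748757410810, -0.016864118442875, -0.078223266528988,
         0.266864118442872, 0.602949018236358, 0.266864118442872,
         -0.078223266528988, -0.016864118442875, 0.026748757410810)
  a / sum(a)
}

cdf97_synthesis_lp <- function() {
  s <- c(-0.045635881557124, -0.028771763114250, 0.295635881557124,
         0.557543526228500, 0.295635881557124, -0.028771763114250,
         -0.045635881557124)
  s / sum(s)
}

# Nonsubsampled Laplacian-pyramid quad from a separable lowpass pair.
laplacian_quad <- function(lp_a, lp_s, name) {
  h0 <- outer(lp_a, lp_a)
  g0 <- outer(lp_s, lp_s)
  h1 <- kernel_lincomb(list(delta_kernel(), conv2_kernels(h0, g0)), c(1, -1))
  g1 <- delta_kernel()
  new_filter_quad(h0, h1, g0, g1, name, "pyramid")
}

#' Pyramid (NSPFB) analysis/synthesis filter quad
#'
#' Builds the two-channel nonsubsampled pyramid bank used for the
#' multi-scale stage. `"9-7"` derives the bank from the CDF 9/7
#' biorthogonal lowpass pair; `"maxflat"` from the maximally flat
#' binomial lowpass. In both cases the high-pass branch is the Laplacian
#' complement, so the Bezout identity holds exactly and the high-pass
#' kernel annihilates constants.
#'
#' @param name `"9-7"` or `"maxflat"`.
#' @return An object of class `nss_filter_quad` with elements
#'   `h0`, `h1` (analysis) and `g0`, `g1` (synthesis).
#' @export
build_pyramid_filters <- function(name) {
  switch(as.character(name)[1],
    "9-7" = laplacian_quad(cdf97_analysis_lp(), cdf97_synthesis_lp(), "9-7"),
    "maxflat" = {
      b <- c(1, 4, 6, 4, 1) / 16
      laplacian_quad(b, b, "maxflat")
    },
    stop_config("unsupported pyramid filter family: '", name, "'")
  )
}

# Coefficients of the Chebyshev polynomial T_n (index i = coefficient of c^(i-1)).
chebyshev_coefs <- function(n) {
  if (n == 0) return(1)
  if (n == 1) return(c(0, 1))
  tm2 <- 1; tm1 <- c(0, 1)
  for (m in 2:n) {
    t <- 2 * c(0, tm1)
    t[seq_along(tm2)] <- t[seq_along(tm2)] - tm2
    tm2 <- tm1; tm1 <- t
  }
  tm1
}

# Fan kernel f with frequency response F(w1,w2) = (1 + P(t))/2, where
# t = (cos w1 - cos w2)/2 is the fan variable (t > 0 on the vertical
# wedge, t < 0 on the horizontal one) and P is an odd polynomial
# approximating sign(t). P is supplied as full power coefficients.
fan_kernel_from_poly <- function(pcoef) {
  tk <- matrix(0, 3L, 3L)
  tk[1L, 2L] <- 0.25; tk[3L, 2L] <- 0.25   # cos(w1)/2: taps at row +/-1
  tk[2L, 1L] <- -0.25; tk[2L, 3L] <- -0.25 # -cos(w2)/2: taps at col +/-1
  attr(tk, "origin") <- c(2L, 2L)
  kernels <- list(delta_kernel())
  coefs <- c(0.5 * (1 + pcoef[1]))
  tpow <- delta_kernel()
  for (d in seq_len(length(pcoef) - 1L)) {
    tpow <- conv2_kernels(tpow, tk)
    if (pcoef[d + 1L] != 0) {
      kernels <- c(kernels, list(tpow))
      coefs <- c(coefs, 0.5 * pcoef[d + 1L])
    }
  }
  kernel_lincomb(kernels, coefs)
}

# Fan quad with exact Bezout identity from a fan kernel f.
fan_quad_from_kernel <- function(f, name) {
  d <- delta_kernel()
  h0 <- f
  g0 <- kernel_lincomb(list(d, f), c(2, -1))
  h1 <- kernel_lincomb(list(d, f), c(1, -1))
  g1 <- h1
  new_filter_quad(h0, h1, g0, g1, name, "fan")
}

#' Fan (NSDFB) analysis/synthesis filter quad
#'
#' Builds the two-channel fan bank that splits the frequency plane into
#' complementary directional wedges. `"pkva"` maps the
#' Phoong-Kim-Vaidyanathan-Ansari ladder half-band filter onto the fan
#' variable via a Chebyshev (McClellan-type) change of variable;
#' `"dmaxflat"` uses the maximally flat odd polynomial of degree 7. Both
#' quads satisfy the Bezout identity exactly, and both analysis filters
#' have magnitude 1/2 at DC (each wedge owns half the origin).
#'
#' @param name `"pkva"` or `"dmaxflat"`.
#' @return An `nss_filter_quad`.
#' @export
build_fan_filters <- function(name) {
  switch(as.character(name)[1],
    "pkva" = {
      # Published ladder coefficients of the pkva12 half-band filter.
      v <- c(0.6300, -0.1930, 0.0972, -0.0526, 0.0272, -0.0144)
      # Q(w) = 2 sum_k v_k cos((2k-1) w) = P(cos w), an odd polynomial
      # stepping from ~+1 at w=0 to ~-1 at w=pi.
      deg <- 2L * length(v) - 1L
      pcoef <- numeric(deg + 1L)
      for (k in seq_along(v)) {
        tc <- chebyshev_coefs(2L * k - 1L)
        pcoef[seq_along(tc)] <- pcoef[seq_along(tc)] + 2 * v[k] * tc
      }
      fan_quad_from_kernel(fan_kernel_from_poly(pcoef), "pkva")
    },
    "dmaxflat" = {
      # Maximally flat odd step polynomial: integral of (1-t^2)^3, normalized.
      pcoef <- c(0, 35, 0, -35, 0, 21, 0, -5) / 16
      fan_quad_from_kernel(fan_kernel_from_poly(pcoef), "dmaxflat")
    },
    stop_config("unsupported fan filter family: '", name, "'")
  )
}

#' Quincunx sampling matrix
#'
#' The 2x2 integer matrix (determinant 2) used to upsample fan filters
#' between directional tree levels, giving the chessboard frequency
#' support.
#'
#' @return A 2x2 integer matrix.
#' @export
quincunx_matrix <- function() {
  matrix(c(1L, 1L, -1L, 1L), 2L, 2L)
}

# Integer power of the quincunx matrix (p = 0 gives the identity).
quincunx_power <- function(p) {
  m <- diag(2L)
  q <- quincunx_matrix()
  for (i in seq_len(p)) m <- m %*% q
  m
}

#' A-trous (zero-insertion) upsampling of a kernel
#'
#' Maps each tap at integer offset `t` (relative to the kernel origin)
#' to offset `m %*% t`, inserting zeros elsewhere. Realizes the
#' `z -> z^M` filter substitutions of the nonsubsampled pyramid
#' (`m = 2^j I`) and directional (`m = quincunx`) cascades without
#' touching the signal.
#'
#' @param kernel Kernel matrix (optionally with an `"origin"` attribute;
#'   defaults to center for odd sizes, top-left otherwise).
#' @param m 2x2 integer matrix with `|det(m)| >= 1`.
#' @return The upsampled kernel with its `"origin"` attribute set.
#' @export
atrous_upsample <- function(kernel, m) {
  stopifnot(is.matrix(kernel), is.matrix(m), all(dim(m) == c(2L, 2L)))
  if (any(abs(m - round(m)) > 1e-9)) stop_config("upsampling matrix must be integer")
  m <- round(m)
  if (abs(det(m)) < 1) stop_config("upsampling matrix must be nonsingular")
  o <- kernel_origin(kernel)
  nz <- which(kernel != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    out <- matrix(0, 1L, 1L)
    attr(out, "origin") <- c(1L, 1L)
    return(out)
  }
  off <- cbind(nz[, 1L] - o[1L], nz[, 2L] - o[2L]) %*% t(m)
  rmin <- min(off[, 1L], 0L); rmax <- max(off[, 1L], 0L)
  cmin <- min(off[, 2L], 0L); cmax <- max(off[, 2L], 0L)
  out <- matrix(0, rmax - rmin + 1L, cmax - cmin + 1L)
  rows <- off[, 1L] - rmin + 1L
  cols <- off[, 2L] - cmin + 1L
  w <- kernel[nz]
  for (t in seq_along(w)) out[rows[t], cols[t]] <- out[rows[t], cols[t]] + w[t]
  attr(out, "origin") <- c(1L - rmin, 1L - cmin)
  out
}

#' Frequency-domain Bezout residual of a filter quad
#'
#' Evaluates `max | H0 G0 + H1 G1 - 1 |` over an `n x n` DFT grid; zero
#' residual is the perfect-reconstruction condition of the undecimated
#' two-channel bank.
#'
#' @param quad An `nss_filter_quad`.
#' @param n Grid size (default 64).
#' @return Maximum absolute residual over the grid.
#' @export
bezout_residual <- function(quad, n = 64L) {
  stopifnot(inherits(quad, "nss_filter_quad"))
  dft <- function(k) {
    o <- kernel_origin(k)
    nz <- which(k != 0, arr.ind = TRUE)
    K <- matrix(0, n, n)
    ir <- ((nz[, 1L] - o[1L]) %% n) + 1L
    ic <- ((nz[, 2L] - o[2L]) %% n) + 1L
    w <- k[nz]
    for (t in seq_along(w)) K[ir[t], ic[t]] <- K[ir[t], ic[t]] + w[t]
    fft(K)
  }
  r <- dft(quad$h0) * dft(quad$g0) + dft(quad$h1) * dft(quad$g1) - 1
  max(abs(r))
}
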