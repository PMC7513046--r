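# High-pass fusion by the Sum-Modified-Laplacian maximum rule.
#
# The Modified Laplacian is a nonnegative second-difference activity
# measure; SML aggregates its square over a small window. Per pixel the
# coefficient with the larger SML is selected (never averaged), which
# favours the in-focus / information-bearing source and suppresses
# pseudo-Gibbs ringing that blending would introduce.

#' Modified Laplacian activity map
#'
#' `ML(i,j) = |2 I(i,j) - I(i-step,j) - I(i+step,j)| +
#' |2 I(i,j) - I(i,j-step) - I(i,j+step)|` with reflected boundary
#' extension. Annihilates constants and linear ramps.
#'
#' @param band Numeric matrix.
#' @param step Coefficient spacing of the second difference (>= 1).
#' @return Nonnegative matrix of the band's size.
#' @export
modified_laplacian <- function(band, step = 1L) {
  stopifnot(is.matrix(band))
  if (step < 1L) stop_config("step must be >= 1")
  if (step >= min(dim(band)))
    stop_input("step (", step, ") must be smaller than the band size")
  up <- translate_reflect(band, -step, 0L)
  dn <- translate_reflect(band, step, 0L)
  lf <- translate_reflect(band, 0L, -step)
  rt <- translate_reflect(band, 0L, step)
  abs(2 * band - up - dn) + abs(2 * band - lf - rt)
}

#' Sum-Modified-Laplacian map
#'
#' Sums the (by default squared) Modified Laplacian over a
#' `(2p+1) x (2q+1)` window with reflected boundary extension.
#'
#' @param ml_map A Modified Laplacian map (nonnegative matrix).
#' @param p,q Window half-sizes (>= 0); `p = q = 0` degenerates to the
#'   (squared) center value.
#' @param squared Square the ML terms before summing (the default).
#' @return Nonnegative matrix of the input's size.
#' @export
sml <- function(ml_map, p = 1L, q = 1L, squared = TRUE) {
  stopifnot(is.matrix(ml_map))
  if (p < 0L || q < 0L) stop_config("window half-sizes must be >= 0")
  x <- if (squared) ml_map^2 else ml_map
  if (p == 0L && q == 0L) return(x)
  k <- matrix(1, 2L * p + 1L, 2L * q + 1L)
  conv2_same(x, k, boundary = "symmetric")
}

#' Fuse one high-pass band pair by the SML-MAX rule
#'
#' Selects, per pixel, the coefficient of the band whose SML clarity is
#' larger; ties go to the first band. Fused coefficients are always a
#' verbatim copy from one input.
#'
#' @param band_a,band_b Band matrices of equal size.
#' @param cfg A [fusion_config()] supplying `sml_step`, `sml_p`,
#'   `sml_q`, `sml_squared`.
#' @return The fused band matrix.
#' @export
sml_max_fuse <- function(band_a, band_b, cfg = fusion_config()) {
  if (!all(dim(band_a) == dim(band_b))) stop_input("band shapes differ")
  sml_a <- sml(modified_laplacian(band_a, cfg$sml_step),
               cfg$sml_p, cfg$sml_q, cfg$sml_squared)
  sml_b <- sml(modified_laplacian(band_b, cfg$sml_step),
               cfg$sml_p, cfg$sml_q, cfg$sml_squared)
  out <- band_b
  sel <- sml_a >= sml_b
  out[sel] <- band_a[sel]
  out
}

# Fuse every directional band of two pyramids (same configuration).
fuse_highpass_bands <- function(pyr_a, pyr_b, cfg) {
  lapply(seq_len(pyr_a$levels), function(l) {
    lapply(seq_along(pyr_a$highpass[[l]]), function(k) {
      sml_max_fuse(pyr_a$highpass[[l]][[k]], pyr_b$highpass[[l]][[k]], cfg)
    })
  })
}
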