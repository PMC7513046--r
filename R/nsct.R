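# Nonsubsampled contourlet transform: a shift-invariant multi-scale,
# multi-direction decomposition. The pyramid stage filters the signal
# with a-trous-upsampled lowpass/highpass kernels (no resampling of the
# signal), and each high-pass band is split into directional wedges by a
# binary tree of fan filters upsampled on the quincunx lattice. Every
# band keeps the size of the source image.

resolve_quad <- function(x, builder) {
  if (inherits(x, "nss_filter_quad")) x else builder(x)
}

is_pow2 <- function(d) d >= 1 && bitwAnd(as.integer(d), as.integer(d) - 1L) == 0L

# Upsampling matrix for directional tree depth d (1-based):
# identity at the first split, quincunx powers deeper down.
dfb_upsampling_matrix <- function(d) quincunx_power(d - 1L)

nsdfb_decompose <- function(band, nbands, fan, boundary) {
  if (nbands == 1L) return(list(band))
  depth <- as.integer(round(log2(nbands)))
  nodes <- list(band)
  for (d in seq_len(depth)) {
    m <- dfb_upsampling_matrix(d)
    h0u <- atrous_upsample(fan$h0, m)
    h1u <- atrous_upsample(fan$h1, m)
    nxt <- vector("list", 2L * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2L * i - 1L]] <- conv2_same(nodes[[i]], h0u, boundary)
      nxt[[2L * i]] <- conv2_same(nodes[[i]], h1u, boundary)
    }
    nodes <- nxt
  }
  nodes
}

nsdfb_reconstruct <- function(bands, fan, boundary) {
  nbands <- length(bands)
  if (nbands == 1L) return(bands[[1L]])
  depth <- as.integer(round(log2(nbands)))
  nodes <- bands
  for (d in depth:1L) {
    m <- dfb_upsampling_matrix(d)
    g0u <- atrous_upsample(fan$g0, m)
    g1u <- atrous_upsample(fan$g1, m)
    nxt <- vector("list", length(nodes) %/% 2L)
    for (i in seq_along(nxt)) {
      nxt[[i]] <- conv2_same(nodes[[2L * i - 1L]], g0u, boundary) +
        conv2_same(nodes[[2L * i]], g1u, boundary)
    }
    nodes <- nxt
  }
  nodes[[1L]]
}

validate_directions <- function(levels, directions) {
  if (length(directions) != levels)
    stop_config("`directions` must have one entry per level (got ",
                length(directions), " for ", levels, " levels)")
  for (d in directions) {
    if (!is_pow2(d))
      stop_config("direction counts must be 1 or a power of two, got ", d)
  }
}

#' NSCT forward decomposition
#'
#' Decomposes an image into one low-pass band and, per scale, a list of
#' directional high-pass bands. All bands have the input's size, the
#' transform is linear, and under periodic boundary handling it is
#' exactly shift-invariant and perfectly invertible by
#' [nsct_reconstruct()].
#'
#' @param img Numeric matrix with finite values.
#' @param levels Number of pyramid scales (>= 1).
#' @param directions Integer vector, one entry per scale, ordered
#'   coarsest to finest; each entry is 1 (no directional split) or a
#'   power of two >= 2.
#' @param pyramid_filter Filter family name (see
#'   [build_pyramid_filters()]) or an `nss_filter_quad`.
#' @param fan_filter Filter family name (see [build_fan_filters()]) or
#'   an `nss_filter_quad`.
#' @param boundary `"symmetric"` or `"periodic"` extension.
#' @return An object of class `nss_pyramid`: a list with `lowpass` (a
#'   matrix), `highpass` (a list over scales, coarsest first, each a
#'   list of directional band matrices), and the configuration used.
#' @export
nsct_decompose <- function(img, levels, directions,
                           pyramid_filter = "9-7", fan_filter = "pkva",
                           boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  stopifnot(is.matrix(img))
  if (!all(is.finite(img))) stop_input("image contains non-finite values")
  if (levels < 1L) stop_config("`levels` must be >= 1")
  validate_directions(levels, directions)
  pyr <- resolve_quad(pyramid_filter, build_pyramid_filters)
  fan <- resolve_quad(fan_filter, build_fan_filters)

  dirs_fine_first <- rev(directions)
  x <- img
  high <- vector("list", levels)
  for (j in seq_len(levels)) {  # j = 1 is the finest scale
    m <- (2L^(j - 1L)) * diag(2L)
    h0j <- atrous_upsample(pyr$h0, m)
    h1j <- atrous_upsample(pyr$h1, m)
    hp <- conv2_same(x, h1j, boundary)
    x <- conv2_same(x, h0j, boundary)
    high[[j]] <- nsdfb_decompose(hp, dirs_fine_first[j], fan, boundary)
  }
  structure(list(lowpass = x,
                 highpass = rev(high),  # coarsest scale first
                 levels = levels,
                 directions = as.integer(directions),
                 pyramid_filter = pyr$name,
                 fan_filter = fan$name,
                 boundary = boundary,
                 dim = dim(img)),
            class = "nss_pyramid")
}

#' @export
print.nss_pyramid <- function(x, ...) {
  cat(sprintf("<nss_pyramid %dx%d: %d levels, directions [%s], filters %s/%s, %s boundary>\n",
              x$dim[1], x$dim[2], x$levels,
              paste(x$directions, collapse = ","),
              x$pyramid_filter, x$fan_filter, x$boundary))
  invisible(x)
}

#' NSCT inverse reconstruction
#'
#' Inverts [nsct_decompose()]. The round trip is exact to
#' floating-point accuracy under both boundary modes: every
#' analysis/synthesis pair used here is a polynomial in a single
#' convolution operator, so the stages commute and the Bezout identity
#' cancels them exactly whatever the extension.
#'
#' @param pyr An `nss_pyramid`.
#' @param pyramid_filter,fan_filter Optional overrides; default to the
#'   families recorded in `pyr`.
#' @param boundary Optional override of the recorded boundary mode.
#' @return The reconstructed image matrix.
#' @export
nsct_reconstruct <- function(pyr, pyramid_filter = NULL, fan_filter = NULL,
                             boundary = NULL) {
  stopifnot(inherits(pyr, "nss_pyramid"))
  pq <- resolve_quad(pyramid_filter %||% pyr$pyramid_filter, build_pyramid_filters)
  fq <- resolve_quad(fan_filter %||% pyr$fan_filter, build_fan_filters)
  boundary <- boundary %||% pyr$boundary
  if (length(pyr$highpass) != pyr$levels)
    stop_input("pyramid has ", length(pyr$highpass), " high-pass groups for ",
               pyr$levels, " levels")
  for (l in seq_len(pyr$levels)) {
    if (length(pyr$highpass[[l]]) != pyr$directions[l])
      stop_input("scale ", l, " has ", length(pyr$highpass[[l]]),
                 " bands, expected ", pyr$directions[l])
    for (b in pyr$highpass[[l]]) {
      if (!all(dim(b) == pyr$dim)) stop_input("band shape mismatch")
    }
  }
  x <- pyr$lowpass
  for (l in seq_len(pyr$levels)) {  # coarsest to finest
    j <- pyr$levels - l + 1L        # pyramid stage index (1 = finest)
    m <- (2L^(j - 1L)) * diag(2L)
    g0j <- atrous_upsample(pq$g0, m)
    g1j <- atrous_upsample(pq$g1, m)
    hp <- nsdfb_reconstruct(pyr$highpass[[l]], fq, boundary)
    x <- conv2_same(x, g0j, boundary) + conv2_same(hp, g1j, boundary)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
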