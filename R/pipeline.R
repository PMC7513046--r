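# End-to-end fusion: NSCT decomposition of both sources, dictionary
# learning on the pair's own low-pass patches, sparse-representation
# low-pass fusion, SML-MAX high-pass fusion, inverse NSCT.

#' Fusion configuration
#'
#' Collects every tunable of the fusion pipeline. The defaults follow
#' the reference operating point: 4 pyramid levels with 4, 8, 8, 16
#' directions from coarsest to finest, the "9-7" pyramid and "pkva" fan
#' filter families, 8 x 8 patches with stride 1, retained-variance
#' fraction `delta = 0.95`, and SML step 1 with a 3 x 3 window.
#'
#' @param levels Pyramid scales.
#' @param directions Directional band counts per scale, coarsest first;
#'   each 1 or a power of two.
#' @param pyramid_filter,fan_filter Filter family names.
#' @param patch_size Patch side length (pixels).
#' @param stride Sliding-window step (pixels).
#' @param eps SOMP residual-norm stopping threshold; defaults to
#'   `0.01 * patch_size` (i.e. a 0.01 RMS error per pixel on \[0,1\] data).
#' @param max_atoms Hard cap on SOMP support size.
#' @param n_clusters Number of joint patch clusters.
#' @param delta Retained eigenvalue mass fraction per cluster, in (0, 1].
#' @param sml_p,sml_q SML window half-sizes.
#' @param sml_step Modified-Laplacian coefficient spacing.
#' @param sml_squared Square ML terms inside the SML window.
#' @param boundary Convolution boundary extension for fusion runs.
#' @param seed RNG seed (clustering initialization).
#' @param color_mode `"luma"` (fuse luminance, pick chroma from the
#'   locally dominant source) or `"per_channel"`.
#' @return An object of class `nss_config`.
#' @export
fusion_config <- function(levels = 4L,
                          directions = c(4L, 8L, 8L, 16L),
                          pyramid_filter = "9-7",
                          fan_filter = "pkva",
                          patch_size = 8L,
                          stride = 1L,
                          eps = NULL,
                          max_atoms = 16L,
                          n_clusters = 8L,
                          delta = 0.95,
                          sml_p = 1L,
                          sml_q = 1L,
                          sml_step = 1L,
                          sml_squared = TRUE,
                          boundary = c("symmetric", "periodic"),
                          seed = 0L,
                          color_mode = c("luma", "per_channel")) {
  boundary <- match.arg(boundary)
  color_mode <- match.arg(color_mode)
  if (levels < 1L) stop_config("levels must be >= 1")
  validate_directions(levels, directions)
  if (patch_size < 2L) stop_config("patch_size must be >= 2")
  if (stride < 1L) stop_config("stride must be >= 1")
  if (is.null(eps)) eps <- 0.01 * patch_size  # 0.01 * sqrt(n pixels)
  if (eps <= 0) stop_config("eps must be > 0")
  if (max_atoms < 1L) stop_config("max_atoms must be >= 1")
  if (n_clusters < 1L) stop_config("n_clusters must be >= 1")
  if (delta <= 0 || delta > 1) stop_config("delta must be in (0, 1]")
  structure(list(levels = as.integer(levels),
                 directions = as.integer(directions),
                 pyramid_filter = pyramid_filter,
                 fan_filter = fan_filter,
                 patch_size = as.integer(patch_size),
                 stride = as.integer(stride),
                 eps = eps,
                 max_atoms = as.integer(max_atoms),
                 n_clusters = as.integer(n_clusters),
                 delta = delta,
                 sml_p = as.integer(sml_p),
                 sml_q = as.integer(sml_q),
                 sml_step = as.integer(sml_step),
                 sml_squared = isTRUE(sml_squared),
                 boundary = boundary,
                 seed = as.integer(seed),
                 color_mode = color_mode),
            class = "nss_config")
}

#' @export
print.nss_config <- function(x, ...) {
  cat(sprintf(paste0("<nss_config: %d levels [%s], filters %s/%s, patch %dx%d ",
                     "stride %d, eps %.4g, K %d, delta %.2f, seed %d>\n"),
              x$levels, paste(x$directions, collapse = ","),
              x$pyramid_filter, x$fan_filter, x$patch_size, x$patch_size,
              x$stride, x$eps, x$n_clusters, x$delta, x$seed))
  invisible(x)
}

#' Fuse two co-registered grayscale images
#'
#' Runs the full pipeline: NSCT decomposition of both sources, joint
#' dictionary learning on the two low-pass bands (unless a dictionary
#' is supplied), sparse-representation low-pass fusion with the Max-L1
#' rule, SML-MAX high-pass fusion, inverse NSCT, and clipping to
#' \[0, 1\]. Deterministic for a fixed `cfg$seed`.
#'
#' @param img_a,img_b Numeric matrices of equal size, values in \[0, 1\],
#'   assumed co-registered.
#' @param cfg A [fusion_config()].
#' @param dictionary Optional pre-trained `nss_dictionary`; by default
#'   one is learned from this pair's low-pass bands.
#' @param details If `TRUE`, return an `nss_fusion` list carrying the
#'   fused image plus intermediates (pyramids' low-pass bands, fused
#'   low-pass, low-pass winner fraction map, dictionary).
#' @return The fused image matrix in \[0, 1\], or an `nss_fusion` list.
#' @export
fuse <- function(img_a, img_b, cfg = fusion_config(), dictionary = NULL,
                 details = FALSE) {
  stopifnot(is.matrix(img_a), is.matrix(img_b))
  if (!all(dim(img_a) == dim(img_b))) stop_input("image shapes differ")
  if (!all(is.finite(img_a)) || !all(is.finite(img_b)))
    stop_input("images contain non-finite pixels")
  pyr_a <- nsct_decompose(img_a, cfg$levels, cfg$directions,
                          cfg$pyramid_filter, cfg$fan_filter, cfg$boundary)
  pyr_b <- nsct_decompose(img_b, cfg$levels, cfg$directions,
                          cfg$pyramid_filter, cfg$fan_filter, cfg$boundary)
  phi <- dictionary %||% learn_dictionary(pyr_a$lowpass, pyr_b$lowpass, cfg)
  low <- fuse_lowpass(pyr_a$lowpass, pyr_b$lowpass, phi, cfg, details = TRUE)
  fused_pyr <- pyr_a
  fused_pyr$lowpass <- low$band
  fused_pyr$highpass <- fuse_highpass_bands(pyr_a, pyr_b, cfg)
  img <- nsct_reconstruct(fused_pyr)
  img <- pmin(pmax(img, 0), 1)
  if (!details) return(img)
  structure(list(image = img,
                 lowpass_a = pyr_a$lowpass,
                 lowpass_b = pyr_b$lowpass,
                 lowpass_fused = low$band,
                 winner_frac = low$winner_frac,
                 dictionary = phi,
                 config = cfg),
            class = "nss_fusion")
}

# BT.601 luma/chroma transform (chroma zero-centered); exact inverse.
rgb_to_ycbcr <- function(x) {
  y <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  cb <- (x[, , 3] - y) / 1.772
  cr <- (x[, , 1] - y) / 1.402
  list(y = y, cb = cb, cr = cr)
}

ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + 1.402 * cr
  b <- y + 1.772 * cb
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 1)
}

#' Fuse two color images
#'
#' In `"luma"` mode the BT.601 luminance channels are fused with
#' [fuse()] and chroma is copied per pixel from whichever source won
#' the majority of low-pass patch selections at that pixel. In
#' `"per_channel"` mode each channel is fused independently.
#'
#' @param img_a,img_b Arrays of dimension `rows x cols x 3` in \[0, 1\].
#' @param cfg A [fusion_config()]; `cfg$color_mode` selects the mode.
#' @return Fused `rows x cols x 3` array in \[0, 1\].
#' @export
fuse_color <- function(img_a, img_b, cfg = fusion_config()) {
  if (length(dim(img_a)) != 3L || length(dim(img_b)) != 3L ||
      dim(img_a)[3] != 3L || dim(img_b)[3] != 3L)
    stop_input("color fusion expects rows x cols x 3 arrays")
  if (!all(dim(img_a) == dim(img_b))) stop_input("image shapes differ")
  if (cfg$color_mode == "per_channel") {
    out <- array(0, dim(img_a))
    for (ch in 1:3) out[, , ch] <- fuse(img_a[, , ch], img_b[, , ch], cfg)
    return(out)
  }
  ya <- rgb_to_ycbcr(img_a)
  yb <- rgb_to_ycbcr(img_b)
  res <- fuse(ya$y, yb$y, cfg, details = TRUE)
  take_a <- res$winner_frac >= 0.5
  cb <- yb$cb; cb[take_a] <- ya$cb[take_a]
  cr <- yb$cr; cr[take_a] <- ya$cr[take_a]
  ycbcr_to_rgb(res$image, cb, cr)
}
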