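# Deterministic synthetic fixtures: multi-focus pairs with an
# all-in-focus ground truth, and pseudo-multi-modal phantom pairs whose
# structures are split between the two modalities. Textures are
# band-limited filtered noise so that second-difference focus measures
# respond strongly.

#' Synthetic multi-focus image pair with ground truth
#'
#' Renders a sharp textured scene (band-limited noise plus a smooth
#' large-scale component), then blurs it inside a mask for source `a`
#' and outside the mask for source `b`, so each source is degraded on a
#' complementary region and the sharp scene is the all-in-focus target.
#'
#' @param size Image size, one number or `c(rows, cols)`.
#' @param blur_sigma Gaussian defocus blur sigma in pixels (> 0).
#' @param split `"left-right"` (mask is the left half) or `"disk"`
#'   (mask is a centered disk of radius `min(size)/3`).
#' @param texture_smooth Sigma of the band-limiting smoother applied to
#'   the noise texture.
#' @param noise_sigma Optional additive Gaussian sensor noise sigma.
#' @param seed RNG seed; the triple is reproducible bit-exactly.
#' @return List with sources `a` and `b`, ground truth `gt`, and the
#'   logical `mask` (TRUE where `a` is blurred).
#' @export
make_multifocus_pair <- function(size = c(256L, 256L), blur_sigma = 3,
                                 split = c("left-right", "disk"),
                                 texture_smooth = 1, noise_sigma = 0,
                                 seed = 0L) {
  split <- match.arg(split)
  if (blur_sigma <= 0) stop_config("blur_sigma must be > 0")
  if (length(size) == 1L) size <- c(size, size)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  with_seed(seed, {
    tex <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), texture_smooth)
    tex <- (tex - min(tex)) / (max(tex) - min(tex))
    low <- gaussian_smooth(matrix(rnorm(nr * nc), nr, nc), max(8, nr / 16))
    low <- (low - min(low)) / (max(low) - min(low))
    gt <- 0.1 + 0.8 * (0.45 * low + 0.55 * tex)
    mask <- if (split == "left-right") {
      matrix(rep(seq_len(nc) <= nc %/% 2L, each = nr), nr, nc)
    } else {
      rr <- outer(seq_len(nr) - (nr + 1) / 2, seq_len(nc) - (nc + 1) / 2,
                  function(i, j) sqrt(i^2 + j^2))
      rr <= min(nr, nc) / 3
    }
    blurred <- gaussian_smooth(gt, blur_sigma)
    a <- gt; a[mask] <- blurred[mask]
    b <- gt; b[!mask] <- blurred[!mask]
    if (noise_sigma > 0) {
      a <- a + noise_sigma * matrix(rnorm(nr * nc), nr, nc)
      b <- b + noise_sigma * matrix(rnorm(nr * nc), nr, nc)
    }
    list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1),
         gt = gt, mask = mask)
  })
}

#' Synthetic pseudo-multi-modal phantom pair
#'
#' Renders one blob phantom (elliptical structures on a dark
#' background) under two disjoint intensity mappings: modality `a`
#' shows the odd-numbered structures at full contrast and suppresses
#' the rest, modality `b` the complement. The union of visible
#' structures is the whole phantom, emulating complementary organ
#' information across modalities.
#'
#' @param size Image size, one number or `c(rows, cols)`.
#' @param n_structures Number of elliptical structures (>= 2).
#' @param seed RNG seed.
#' @return List with `a`, `b`, the logical structure `masks`, and
#'   `visible_in` (`"a"` or `"b"` per structure).
#' @export
make_multimodal_pair <- function(size = c(256L, 256L), n_structures = 6L,
                                 seed = 0L) {
  if (n_structures < 2L) stop_config("need at least 2 structures")
  if (length(size) == 1L) size <- c(size, size)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  with_seed(seed, {
    bg <- 0.05
    a <- matrix(bg, nr, nc)
    b <- matrix(bg, nr, nc)
    ii <- matrix(seq_len(nr), nr, nc)
    jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    masks <- vector("list", n_structures)
    visible_in <- character(n_structures)
    # structures on a jittered ring so they never overlap the border
    ang <- seq(0, 2 * pi, length.out = n_structures + 1L)[seq_len(n_structures)]
    for (s in seq_len(n_structures)) {
      cy <- nr / 2 + 0.28 * nr * sin(ang[s]) + runif(1, -0.03, 0.03) * nr
      cx <- nc / 2 + 0.28 * nc * cos(ang[s]) + runif(1, -0.03, 0.03) * nc
      ry <- runif(1, 0.06, 0.11) * nr
      rx <- runif(1, 0.06, 0.11) * nc
      val <- runif(1, 0.5, 0.9)
      m <- ((ii - cy) / ry)^2 + ((jj - cx) / rx)^2 <= 1
      masks[[s]] <- m
      if (s %% 2L == 1L) {
        a[m] <- val
        visible_in[s] <- "a"
      } else {
        b[m] <- val
        visible_in[s] <- "b"
      }
    }
    a <- gaussian_smooth(a, 1)
    b <- gaussian_smooth(b, 1)
    list(a = pmin(pmax(a, 0), 1), b = pmin(pmax(b, 0), 1),
         masks = masks, visible_in = visible_in)
  })
}
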