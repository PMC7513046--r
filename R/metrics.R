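# Objective fusion-quality metrics: mutual information between each
# source and the fused image, the Xydeas-Petrovic gradient-preservation
# index QAB/F, and Yang's structural-similarity-based index QY.

bin_image <- function(x, bins) {
  pmin(pmax(floor(x * bins), 0), bins - 1L)
}

binned_entropy <- function(x, bins = 256L) {
  p <- tabulate(bin_image(x, bins) + 1L, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

mi_pair <- function(x, y, bins) {
  bx <- bin_image(x, bins); by <- bin_image(y, bins)
  j <- tabulate(bx * bins + by + 1L, nbins = bins * bins)
  pj <- j / sum(j)
  px <- rowSums(matrix(pj, bins, bins, byrow = TRUE))
  py <- colSums(matrix(pj, bins, bins, byrow = TRUE))
  nz <- pj > 0
  outerp <- as.vector(t(outer(px, py)))
  sum(pj[nz] * log2(pj[nz] / outerp[nz]))
}

#' Mutual information fusion metric
#'
#' `MI = I(A; F) + I(B; F)` from joint intensity histograms, in bits;
#' no normalization is applied. A constant fused image gives 0.
#'
#' @param a,b Source image matrices in \[0, 1\].
#' @param f Fused image matrix in \[0, 1\].
#' @param bins Histogram bin count (256 suits 8-bit data).
#' @return Nonnegative scalar.
#' @export
mutual_information <- function(a, b, f, bins = 256L) {
  stopifnot(all(dim(a) == dim(f)), all(dim(b) == dim(f)))
  if (bins < 2L) stop_config("bins must be >= 2")
  mi_pair(a, f, bins) + mi_pair(b, f, bins)
}

sobel_gradients <- function(x) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)        # d/dcol
  ky <- t(kx)                                                   # d/drow
  gx <- conv2_same(x, kx, boundary = "symmetric")
  gy <- conv2_same(x, ky, boundary = "symmetric")
  g <- sqrt(gx^2 + gy^2)
  alpha <- atan2(gy, gx)
  alpha[alpha > pi / 2] <- alpha[alpha > pi / 2] - pi
  alpha[alpha <= -pi / 2] <- alpha[alpha <= -pi / 2] + pi
  list(g = g, alpha = alpha)
}

# Per-pixel edge-preservation factor between a source and the fused image.
edge_preservation <- function(src, fus) {
  # Published sigmoid constants of the gradient metric.
  Gg <- 0.9994; kg <- -15; sg <- 0.5
  Ga <- 0.9879; ka <- -22; sa <- 0.8
  hi <- pmax(src$g, fus$g)
  lo <- pmin(src$g, fus$g)
  G <- ifelse(hi > 0, lo / hi, 0)
  d <- abs(src$alpha - fus$alpha)
  d <- pmin(d, pi - d)
  A <- 1 - d / (pi / 2)
  Qg <- Gg / (1 + exp(kg * (G - sg)))
  Qa <- Ga / (1 + exp(ka * (A - sa)))
  Qg * Qa
}

#' Gradient-based fusion quality index (QAB/F)
#'
#' Xydeas-Petrovic edge-transfer metric: per-pixel preservation of
#' Sobel edge strength and orientation from each source into the fused
#' image, weighted by source edge strength. Ranges over \[0, 1\]; two
#' flat sources give 0 by convention (no edges to preserve).
#'
#' @param a,b Source image matrices.
#' @param f Fused image matrix.
#' @return Scalar in \[0, 1\].
#' @export
q_abf <- function(a, b, f) {
  stopifnot(all(dim(a) == dim(f)), all(dim(b) == dim(f)))
  ga <- sobel_gradients(a)
  gb <- sobel_gradients(b)
  gf <- sobel_gradients(f)
  qaf <- edge_preservation(ga, gf)
  qbf <- edge_preservation(gb, gf)
  wa <- ga$g
  wb <- gb$g
  denom <- sum(wa + wb)
  # numerically flat sources carry no edge information to preserve
  if (denom <= 1e-8 * length(a)) return(0)
  val <- sum(qaf * wa + qbf * wb) / denom
  min(max(val, 0), 1)
}

box_mean <- function(x, r) {
  k <- matrix(1 / (2 * r + 1)^2, 2L * r + 1L, 2L * r + 1L)
  conv2_same(x, k, boundary = "symmetric")
}

local_stats <- function(x, y, r) {
  mx <- box_mean(x, r); my <- box_mean(y, r)
  vx <- pmax(box_mean(x^2, r) - mx^2, 0)
  vy <- pmax(box_mean(y^2, r) - my^2, 0)
  cxy <- box_mean(x * y, r) - mx * my
  C1 <- 0.01^2; C2 <- 0.03^2
  ssim <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  list(ssim = ssim, vx = vx, vy = vy)
}

#' Yang's structural fusion quality index (QY)
#'
#' Windowed structural similarity with variance-weighted switching:
#' where the two sources are locally similar (SSIM >= 0.75) the fused
#' window is compared against a variance-weighted blend of both
#' source similarities; elsewhere against the better-matching source
#' only. Equals 1 when the fused image coincides with both sources.
#'
#' @param a,b Source image matrices.
#' @param f Fused image matrix.
#' @param window Odd window side length (>= 3).
#' @return Scalar in \[0, 1\].
#' @export
q_y <- function(a, b, f, window = 7L) {
  stopifnot(all(dim(a) == dim(f)), all(dim(b) == dim(f)))
  if (window < 3L || window %% 2L == 0L)
    stop_config("window must be odd and >= 3")
  r <- (window - 1L) %/% 2L
  ab <- local_stats(a, b, r)
  af <- local_stats(a, f, r)
  bf <- local_stats(b, f, r)
  lam <- ifelse(ab$vx + ab$vy > 0, ab$vx / (ab$vx + ab$vy), 0.5)
  q <- ifelse(ab$ssim >= 0.75,
              lam * af$ssim + (1 - lam) * bf$ssim,
              pmax(af$ssim, bf$ssim))
  min(max(mean(q), 0), 1)
}

#' All fusion metrics as one report
#'
#' @param a,b Source image matrices.
#' @param f Fused image matrix.
#' @param bins Histogram bins for mutual information.
#' @param window Window size for QY.
#' @return Named list with `mi`, `q_abf`, `q_y` (fields for further
#'   metrics are reserved as `NA`).
#' @export
fusion_metrics <- function(a, b, f, bins = 256L, window = 7L) {
  list(mi = mutual_information(a, b, f, bins),
       q_abf = q_abf(a, b, f),
       q_y = q_y(a, b, f, window),
       q_te = NA_real_, q_ie = NA_real_, q_p = NA_real_,
       q_cb = NA_real_, vif = NA_real_)
}
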