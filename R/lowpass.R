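# Sparse-representation fusion of the two low-pass bands.
#
# Per sliding-window position: the two zero-mean patch vectors are
# jointly sparse-coded with SOMP on a shared atom support; the code
# with the larger l1 norm wins (ties to the second source); the fused
# patch is the winner's code expanded on the dictionary plus the
# winner's stored mean; patches are re-assembled by overlap-add and
# each pixel divided by its coverage count.

new_sparse_code <- function(coefficients, support, residual_norm) {
  structure(list(coefficients = coefficients,
                 support = as.integer(support),
                 residual_norm = residual_norm),
            class = "nss_sparse_code")
}

#' Joint sparse coding of a patch-vector pair (SOMP)
#'
#' Greedily selects atoms maximizing the summed absolute correlation
#' with both residuals, so the two codes share one support; each
#' signal's coefficients are its least-squares fit on that support.
#' Stops when both residual norms are at most `eps` or `max_atoms`
#' atoms have been selected.
#'
#' @param v_a,v_b Zero-mean numeric vectors of length `nrow(phi$atoms)`.
#' @param phi An `nss_dictionary`.
#' @param eps Residual-norm stopping threshold (> 0).
#' @param max_atoms Hard cap on the support size.
#' @return A list of two `nss_sparse_code` objects (`a`, `b`), each with
#'   full-length `coefficients`, the shared `support` (1-based), and
#'   `residual_norm`.
#' @export
somp_encode <- function(v_a, v_b, phi, eps = 0.08, max_atoms = 16L) {
  stopifnot(inherits(phi, "nss_dictionary"))
  if (ncol(phi$atoms) == 0L) stop_input("dictionary has no atoms")
  n <- nrow(phi$atoms)
  if (length(v_a) != n || length(v_b) != n)
    stop_input("vector length (", length(v_a), ", ", length(v_b),
               ") does not match dictionary row count (", n, ")")
  if (eps <= 0) stop_config("eps must be > 0")
  r <- somp_encode_cpp(phi$atoms, as.numeric(v_a), as.numeric(v_b),
                       eps, as.integer(max_atoms))
  list(a = new_sparse_code(r$coef_a, r$support, r$residual_a),
       b = new_sparse_code(r$coef_b, r$support, r$residual_b))
}

#' Max-L1 selection between two sparse codes
#'
#' Returns the code with the larger l1 norm; on a tie the second code
#' wins (the literal "otherwise" branch), so fusing an image with
#' itself deterministically selects source B everywhere. The winner's
#' identity drives the mean selection in patch reconstruction.
#'
#' @param alpha_a,alpha_b `nss_sparse_code` objects over one dictionary.
#' @return The winning `nss_sparse_code` with a `winner` element
#'   (`"A"` or `"B"`) added.
#' @export
max_l1_fuse <- function(alpha_a, alpha_b) {
  stopifnot(inherits(alpha_a, "nss_sparse_code"),
            inherits(alpha_b, "nss_sparse_code"))
  if (length(alpha_a$coefficients) != length(alpha_b$coefficients))
    stop_input("codes are over dictionaries of different sizes")
  a_wins <- sum(abs(alpha_a$coefficients)) > sum(abs(alpha_b$coefficients))
  out <- if (a_wins) alpha_a else alpha_b
  out$winner <- if (a_wins) "A" else "B"
  out
}

#' Rebuild a fused patch vector from its fused code
#'
#' Expands the fused code on the dictionary and restores the mean of
#' whichever source won the Max-L1 selection.
#'
#' @param alpha_f Fused `nss_sparse_code`.
#' @param winner `"A"` or `"B"`.
#' @param mean_a,mean_b Stored patch means of the two sources.
#' @param phi An `nss_dictionary`.
#' @return Numeric patch vector of length `nrow(phi$atoms)`.
#' @export
reconstruct_fused_patch <- function(alpha_f, winner, mean_a, mean_b, phi) {
  winner <- match.arg(winner, c("A", "B"))
  v <- as.numeric(phi$atoms %*% alpha_f$coefficients)
  v + if (winner == "A") mean_a else mean_b
}

#' Fuse two low-pass bands by sparse representation
#'
#' Applies the SOMP / Max-L1 / mean-restore steps at every sliding
#' window position and reassembles the fused band by overlap-add,
#' dividing each pixel by the number of windows covering it.
#'
#' @param l_a,l_b Low-pass band matrices of equal size.
#' @param phi An `nss_dictionary` whose atom dimension is
#'   `cfg$patch_size^2`.
#' @param cfg A [fusion_config()].
#' @param details If `TRUE`, also return the per-pixel fraction of
#'   covering windows won by source A.
#' @return The fused band matrix, or (with `details`) a list with
#'   `band` and `winner_frac`.
#' @export
fuse_lowpass <- function(l_a, l_b, phi, cfg = fusion_config(), details = FALSE) {
  if (!all(dim(l_a) == dim(l_b))) stop_input("band shapes differ")
  stopifnot(inherits(phi, "nss_dictionary"))
  if (nrow(phi$atoms) != cfg$patch_size^2)
    stop_input("dictionary atom dimension (", nrow(phi$atoms),
               ") does not match patch_size^2 (", cfg$patch_size^2, ")")
  pa <- extract_patches(l_a, cfg$patch_size, cfg$stride)
  pb <- extract_patches(l_b, cfg$patch_size, cfg$stride)
  core <- fuse_lowpass_core_cpp(phi$atoms, pa$vectors, pb$vectors,
                                pa$means, pb$means, cfg$eps,
                                as.integer(cfg$max_atoms))
  li <- patch_indices(dim(l_a), cfg$patch_size, cfg$stride)
  npix <- prod(dim(l_a))
  counts <- tabulate(li, nbins = npix)
  sums <- numeric(npix)
  agg <- rowsum(as.vector(core$fused), as.vector(li))
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  if (any(counts == 0L))
    stop_config("stride ", cfg$stride, " leaves pixels uncovered; ",
                "use a stride <= patch_size")
  band <- matrix(sums / counts, nrow(l_a), ncol(l_a))
  if (!details) return(band)
  wa <- rep(as.numeric(core$winner == 0L), each = nrow(li))
  aggw <- rowsum(wa, as.vector(li))
  wsum <- numeric(npix)
  wsum[as.integer(rownames(aggw))] <- aggw[, 1L]
  list(band = band,
       winner_frac = matrix(wsum / counts, nrow(l_a), ncol(l_a)))
}
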