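test_that("SOMP recovers exact one-atom signals and empty signals", {
  phi <- random_orthonormal_dictionary(16, seed = 51)
  atom5 <- phi$atoms[, 5]
  r <- somp_encode(3 * atom5, 3 * atom5, phi, eps = 1e-10)
  expect_equal(r$a$support, 5L)
  expect_equal(r$a$coefficients[5], 3, tolerance = 1e-12)
  expect_equal(r$b$coefficients[5], 3, tolerance = 1e-12)
  expect_lt(r$a$residual_norm, 1e-10)
  # zeros outside the support
  expect_equal(sum(r$a$coefficients[-5] != 0), 0L)

  rz <- somp_encode(rep(0, 16), rep(0, 16), phi, eps = 1e-10)
  expect_length(rz$a$support, 0L)
  expect_equal(rz$a$residual_norm, 0)
})

test_that("SOMP selects a shared support and honors its stopping contract", {
  set.seed(52)
  phi <- random_orthonormal_dictionary(32, seed = 52)
  S <- c(3L, 11L, 20L)
  va <- phi$atoms[, S] %*% c(1.0, -0.7, 0.4)
  vb <- phi$atoms[, S] %*% c(-0.5, 0.9, 1.2)
  r <- somp_encode(as.numeric(va), as.numeric(vb), phi, eps = 1e-8,
                   max_atoms = 16L)
  expect_setequal(r$a$support, S)
  expect_identical(r$a$support, r$b$support)
  expect_lt(r$a$residual_norm, 1e-8)
  expect_lt(r$b$residual_norm, 1e-8)

  # max_atoms cap binds when eps is unreachable
  vr <- rnorm(32)
  rc <- somp_encode(vr, vr, phi, eps = 1e-12, max_atoms = 4L)
  expect_length(rc$a$support, 4L)
})

test_that("SOMP validates its inputs", {
  phi <- random_orthonormal_dictionary(16, seed = 53)
  expect_error(somp_encode(rep(0, 9), rep(0, 9), phi), "match")
  empty <- as_dict(matrix(0, 16, 0))
  expect_error(somp_encode(rep(0, 16), rep(0, 16), empty), "no atoms")
})

test_that("Max-L1 selects the larger-l1 code and breaks ties toward B", {
  mk <- function(coefs) {
    structure(list(coefficients = coefs,
                   support = which(coefs != 0),
                   residual_norm = 0),
              class = "nss_sparse_code")
  }
  a <- mk(c(0.5, rep(0, 7)))
  b <- mk(c(0, 0.3, rep(0, 6)))
  expect_equal(max_l1_fuse(a, b)$winner, "A")
  expect_equal(max_l1_fuse(b, a)$winner, "B")
  # exact tie -> B
  b2 <- mk(c(0, 0.5, rep(0, 6)))
  f <- max_l1_fuse(a, b2)
  expect_equal(f$winner, "B")
  expect_equal(f$coefficients, b2$coefficients)
  # identical codes: B label, identical coefficients
  f2 <- max_l1_fuse(a, a)
  expect_equal(f2$winner, "B")
  expect_equal(f2$coefficients, a$coefficients)
})

test_that("fused patch reconstruction restores the winner's mean", {
  phi <- random_orthonormal_dictionary(16, seed = 55)
  zero <- somp_encode(rep(0, 16), rep(0, 16), phi, eps = 1e-10)$a
  p <- reconstruct_fused_patch(zero, "A", mean_a = 0.7, mean_b = 0.1, phi)
  expect_equal(p, rep(0.7, 16))
  one <- somp_encode(2 * phi$atoms[, 3], 2 * phi$atoms[, 3], phi,
                     eps = 1e-10)$a
  p2 <- reconstruct_fused_patch(one, "B", 0, 0.25, phi)
  expect_equal(p2, as.numeric(2 * phi$atoms[, 3]) + 0.25, tolerance = 1e-10)
})

test_that("low-pass self-fusion is near-identity (idempotence)", {
  mf <- make_multifocus_pair(size = 48, blur_sigma = 2, seed = 6)
  cfg <- fusion_config(levels = 2, directions = c(2, 4), stride = 1,
                       n_clusters = 4)
  L <- nsct_decompose(mf$gt, 2, c(2, 4))$lowpass
  phi <- learn_dictionary(L, L, cfg)
  out <- fuse_lowpass(L, L, phi, cfg)
  # per-patch SOMP residuals are bounded by eps; overlap averaging keeps
  # the worst pixel within that bound and the typical error far below it
  expect_lt(max(abs(out - L)), cfg$eps)
  expect_lt(rmse(out, L), 5e-3)
})

test_that("two constant bands fuse to the second constant (zero codes, tie rule)", {
  c1 <- matrix(0.8, 24, 24)
  c2 <- matrix(0.3, 24, 24)
  cfg <- fusion_config(levels = 1, directions = 1, stride = 1)
  expect_warning(phi <- learn_dictionary(c1, c2, cfg), "empty cluster")
  out <- fuse_lowpass(c1, c2, phi, cfg)
  expect_equal(out, c2, tolerance = 1e-12)
})

test_that("fused band stays within the inputs' range up to the coding error", {
  mf <- make_multifocus_pair(size = 40, blur_sigma = 2, seed = 8)
  cfg <- fusion_config(levels = 1, directions = 1, stride = 1, n_clusters = 4)
  phi <- learn_dictionary(mf$a, mf$b, cfg)
  out <- fuse_lowpass(mf$a, mf$b, phi, cfg)
  m <- cfg$eps  # residual bound per patch
  expect_gte(min(out), min(mf$a, mf$b) - m)
  expect_lte(max(out), max(mf$a, mf$b) + m)
  # determinism
  expect_identical(out, fuse_lowpass(mf$a, mf$b, phi, cfg))
})

test_that("overlap-add coverage counts match the window combinatorics", {
  # corner pixel of a large band is covered by exactly 1 window, the
  # center by patch_size^2 windows (stride 1): fusing two bands that
  # differ by a constant exposes the counts through exactness instead;
  # verify directly on the index grid.
  li <- nssfuse:::patch_indices(c(32L, 32L), 8L, 1L)
  counts <- tabulate(li, nbins = 32L * 32L)
  expect_equal(counts[1], 1L)                         # corner
  expect_equal(counts[(15L) * 32L + 16L], 64L)        # center pixel (16,16)
})
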