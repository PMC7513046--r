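test_that("patch extraction counts, positions and mean removal are exact", {
  b <- rand_image(16, seed = 21)
  ps <- extract_patches(b, 8L, 1L)
  expect_equal(ncol(ps$vectors), 81L)            # (16 - 8 + 1)^2
  expect_lt(max(abs(colMeans(ps$vectors))), 1e-12)
  expect_true(all(ps$positions >= 1L))
  expect_true(all(ps$positions <= 9L))
  # column-major vectorization: first patch is the top-left 8x8 block
  expect_equal(ps$vectors[, 1] + ps$means[1], as.vector(b[1:8, 1:8]))

  ps2 <- extract_patches(b, 8L, 4L)
  expect_equal(ncol(ps2$vectors), 9L)            # (floor(8/4)+1)^2
  expect_true(all((ps2$positions - 1L) %% 4L == 0L))
})

test_that("a constant band yields zero vectors with the constant as mean", {
  b <- matrix(0.42, 12, 12)
  ps <- extract_patches(b, 4L, 2L)
  expect_equal(max(abs(ps$vectors)), 0)
  expect_true(all(ps$means == 0.42))
})

test_that("patches larger than the band are rejected", {
  expect_error(extract_patches(matrix(0, 6, 6), 8L), "exceeds")
})

test_that("joint clustering separates distinct patch populations", {
  flat <- matrix(0.5, 24, 24)
  stripes <- matrix(rep(c(0, 1), length.out = 24), 24, 24)
  pa <- extract_patches(flat, 4L, 4L)
  pb <- extract_patches(stripes, 4L, 4L)
  cl <- joint_cluster(pa, pb, 2L, seed = 5)
  na <- ncol(pa$vectors)
  labels_a <- cl[seq_len(na)]
  labels_b <- cl[-seq_len(na)]
  expect_length(unique(labels_a), 1L)
  expect_length(unique(labels_b), 1L)
  expect_false(labels_a[1] == labels_b[1])
})

test_that("clustering is deterministic given the seed and k = 1 is trivial", {
  b1 <- rand_image(20, seed = 31); b2 <- rand_image(20, seed = 32)
  pa <- extract_patches(b1, 4L, 2L); pb <- extract_patches(b2, 4L, 2L)
  expect_identical(joint_cluster(pa, pb, 4L, seed = 9),
                   joint_cluster(pa, pb, 4L, seed = 9))
  expect_true(all(joint_cluster(pa, pb, 1L, seed = 0) == 1L))
  expect_error(joint_cluster(pa, pb, 10000L, seed = 0), "exceeds")
})

test_that("PCA sub-dictionary selects the smallest p reaching the delta mass", {
  # construct a cluster whose second-moment eigenvalues are [0.80, 0.15, 0.05]
  set.seed(41)
  n <- 8L; m <- 12L
  U <- qr.Q(qr(matrix(rnorm(n * n), n)))[, 1:3]
  W <- qr.Q(qr(matrix(rnorm(m * 3), m)))[, 1:3]
  lam <- c(0.80, 0.15, 0.05)
  X <- U %*% diag(sqrt(lam * m)) %*% t(W)
  sd1 <- pca_subdictionary(X, delta = 0.95)
  expect_equal(ncol(sd1$atoms), 2L)
  expect_equal(sd1$eigenvalues, lam[1:2], tolerance = 1e-9)
  # atoms orthonormal
  expect_equal(crossprod(sd1$atoms), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # delta = 1 keeps the full rank
  expect_equal(ncol(pca_subdictionary(X, delta = 1)$atoms), 3L)
})

test_that("degenerate clusters are flagged and rank-1 clusters give one atom", {
  z <- matrix(0, 16, 5)
  sdz <- pca_subdictionary(z, 0.95)
  expect_true(sdz$degenerate)
  expect_equal(ncol(sdz$atoms), 0L)

  v <- rnorm(16); v <- v - mean(v)
  X <- matrix(v, 16, 6)
  sd1 <- pca_subdictionary(X, 0.95)
  expect_equal(ncol(sd1$atoms), 1L)
  expect_equal(abs(sum(sd1$atoms * v / sqrt(sum(v^2)))), 1, tolerance = 1e-10)
})

test_that("aggregate dictionary concatenates sub-dictionaries with offsets", {
  set.seed(43)
  mk <- function(p) {
    a <- qr.Q(qr(matrix(rnorm(36), 6)))[, seq_len(p), drop = FALSE]
    structure(list(atoms = a, eigenvalues = rep(1, p), cluster_id = p,
                   degenerate = FALSE), class = "nss_subdict")
  }
  d <- build_dictionary(list(mk(2), mk(3)))
  expect_equal(ncol(d$atoms), 5L)
  expect_equal(d$cluster_offsets, c(0L, 2L))
  expect_equal(sqrt(colSums(d$atoms^2)), rep(1, 5), tolerance = 1e-10)
  empty <- structure(list(atoms = matrix(0, 6, 0), eigenvalues = numeric(0),
                          cluster_id = 1L, degenerate = TRUE),
                     class = "nss_subdict")
  expect_error(build_dictionary(list(empty)), "empty")
})

test_that("learned dictionary is deterministic, compact, and represents its training data", {
  mf <- make_multifocus_pair(size = 48, blur_sigma = 2, seed = 3)
  cfg <- fusion_config(levels = 2, directions = c(2, 4), stride = 2,
                       n_clusters = 4, patch_size = 8)
  la <- nsct_decompose(mf$a, 2, c(2, 4))$lowpass
  lb <- nsct_decompose(mf$b, 2, c(2, 4))$lowpass
  d1 <- learn_dictionary(la, lb, cfg)
  d2 <- learn_dictionary(la, lb, cfg)
  expect_identical(d1, d2)

  pa <- extract_patches(la, 8L, 2L); pb <- extract_patches(lb, 8L, 2L)
  pooled <- ncol(pa$vectors) + ncol(pb$vectors)
  expect_lt(ncol(d1$atoms), pooled)       # compact vs. raw patch pool
  expect_lte(ncol(d1$atoms), 64L * 4L)

  # projection residual over the pooled training patches is bounded by
  # the discarded eigenvalue mass: <= (1 - delta) of total variance
  X <- cbind(pa$vectors, pb$vectors)
  P <- d1$atoms %*% solve(crossprod(d1$atoms), t(d1$atoms))
  R <- X - P %*% X
  expect_lte(mean(colSums(R^2)), (1 - cfg$delta) * mean(colSums(X^2)) + 1e-9)
})

test_that("dictionary save/load round-trips through plain text", {
  d <- random_orthonormal_dictionary(16, seed = 77)
  d$cluster_offsets <- c(0L, 7L)
  path <- tempfile(fileext = ".txt")
  save_dictionary(d, path)
  d2 <- load_dictionary(path)
  expect_equal(d2$atoms, d$atoms, tolerance = 1e-15)
  expect_equal(d2$cluster_offsets, d$cluster_offsets)
  expect_equal(d2$patch_size, d$patch_size)
  expect_error(load_dictionary(tempfile()), "not found")
})
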