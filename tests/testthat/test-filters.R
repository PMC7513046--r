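test_that("pyramid filter quads satisfy the Bezout identity and DC contracts", {
  for (name in c("9-7", "maxflat")) {
    q <- build_pyramid_filters(name)
    expect_lt(bezout_residual(q, 64L), 1e-10)
    expect_equal(sum(q$h0), 1, tolerance = 1e-12)   # unit DC gain
    expect_lt(abs(sum(q$h1)), 1e-12)                # high-pass kills constants
  }
})

test_that("fan filter quads satisfy the Bezout identity and split DC evenly", {
  for (name in c("pkva", "dmaxflat")) {
    q <- build_fan_filters(name)
    expect_lt(bezout_residual(q, 64L), 1e-8)
    expect_equal(abs(sum(q$h0)), abs(sum(q$h1)), tolerance = 1e-12)
  }
})

test_that("fan filters have complementary wedge-shaped frequency support", {
  q <- build_fan_filters("pkva")
  n <- 64L
  dft <- function(k) {
    o <- c((nrow(k) + 1L) %/% 2L, (ncol(k) + 1L) %/% 2L)
    K <- matrix(0, n, n)
    nz <- which(k != 0, arr.ind = TRUE)
    for (t in seq_len(nrow(nz))) {
      ir <- ((nz[t, 1] - o[1]) %% n) + 1
      ic <- ((nz[t, 2] - o[2]) %% n) + 1
      K[ir, ic] <- K[ir, ic] + k[nz[t, 1], nz[t, 2]]
    }
    Re(fft(K))
  }
  H0 <- dft(q$h0)
  w <- 2 * pi * (0:(n - 1)) / n
  w <- ifelse(w > pi, w - 2 * pi, w)
  W1 <- matrix(w, n, n)          # row frequency
  W2 <- t(W1)                    # column frequency
  inside <- abs(W1) < abs(W2) - 0.6   # deep inside the vertical wedge
  outside <- abs(W1) > abs(W2) + 0.6  # deep inside the complementary wedge
  expect_gt(mean(H0[inside]), 0.95)
  expect_lt(mean(abs(H0[outside])), 0.05)
})

test_that("unknown filter family names are rejected", {
  expect_error(build_pyramid_filters("nonsense"), "unsupported")
  expect_error(build_fan_filters(""), "unsupported")
})

test_that("a-trous upsampling maps taps through the sampling matrix", {
  k <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(atrous_upsample(k, diag(2)), k, ignore_attr = TRUE)

  up <- atrous_upsample(matrix(1, 2, 2), 2 * diag(2))
  expect_equal(dim(up), c(3L, 3L))
  expect_equal(up, matrix(c(1, 0, 1, 0, 0, 0, 1, 0, 1), 3, 3),
               ignore_attr = TRUE)

  # tap multiset (hence filter DC gain) is preserved for any matrix
  q <- quincunx_matrix()
  f <- build_fan_filters("pkva")$h0
  expect_equal(sum(atrous_upsample(f, q)), sum(f))
  expect_equal(sum(atrous_upsample(f, 4 * diag(2))), sum(f))
})

test_that("a-trous upsampling rejects bad matrices", {
  k <- matrix(1, 3, 3)
  expect_error(atrous_upsample(k, matrix(c(0.5, 0, 0, 1), 2, 2)), "integer")
  expect_error(atrous_upsample(k, matrix(c(1, 1, 1, 1), 2, 2)), "nonsingular")
})

test_that("quincunx matrix has determinant of magnitude 2", {
  expect_equal(abs(det(quincunx_matrix())), 2)
})

test_that("upsampled quads keep the Bezout identity (filter substitution)", {
  f <- build_fan_filters("pkva")
  q <- quincunx_matrix()
  up <- f
  up$h0 <- atrous_upsample(f$h0, q); up$h1 <- atrous_upsample(f$h1, q)
  up$g0 <- atrous_upsample(f$g0, q); up$g1 <- atrous_upsample(f$g1, q)
  expect_lt(bezout_residual(up, 64L), 1e-8)
})
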