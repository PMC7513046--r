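test_that("decomposition produces same-size bands with the configured counts", {
  x <- rand_image(48, 40, seed = 3)
  p <- nsct_decompose(x, 3, c(2, 4, 8))
  expect_s3_class(p, "nss_pyramid")
  expect_equal(dim(p$lowpass), dim(x))
  expect_equal(lengths(p$highpass), c(2L, 4L, 8L))
  for (lvl in p$highpass) for (b in lvl) expect_equal(dim(b), dim(x))
})

test_that("a constant image puts everything in the low-pass band", {
  x <- matrix(0.37, 32, 32)
  for (boundary in c("symmetric", "periodic")) {
    p <- nsct_decompose(x, 2, c(2, 4), boundary = boundary)
    expect_lt(max(abs(unlist(p$highpass))), 1e-8)
    expect_equal(p$lowpass, x, tolerance = 1e-10)  # unit DC gain
  }
})

test_that("round trip is exact for random images under both boundary modes", {
  for (s in 1:5) {
    x <- rand_image(40, seed = 100 + s)
    for (boundary in c("periodic", "symmetric")) {
      p <- nsct_decompose(x, 2, c(2, 4), boundary = boundary)
      expect_lt(max(abs(nsct_reconstruct(p) - x)), 1e-6)
    }
  }
})

test_that("round trip on zeros is exactly zero and preserves a delta peak", {
  z <- matrix(0, 32, 32)
  expect_equal(nsct_reconstruct(nsct_decompose(z, 2, c(2, 4))), z)
  d <- matrix(0, 33, 33); d[17, 17] <- 1
  r <- nsct_reconstruct(nsct_decompose(d, 2, c(4, 4)))
  expect_equal(which.max(r), which.max(d))
})

test_that("the transform is shift invariant under periodic extension", {
  x <- rand_image(48, seed = 7)
  p <- nsct_decompose(x, 2, c(2, 4), boundary = "periodic")
  ps <- nsct_decompose(circ_shift(x, 5, 3), 2, c(2, 4), boundary = "periodic")
  expect_lt(max(abs(ps$lowpass - circ_shift(p$lowpass, 5, 3))), 1e-6)
  for (l in seq_along(p$highpass)) {
    for (k in seq_along(p$highpass[[l]])) {
      expect_lt(max(abs(ps$highpass[[l]][[k]] -
                          circ_shift(p$highpass[[l]][[k]], 5, 3))), 1e-6)
    }
  }
})

test_that("the transform is linear band-wise", {
  x <- rand_image(32, seed = 11)
  y <- rand_image(32, seed = 12)
  a <- 0.7; b <- -1.3
  pc <- nsct_decompose(a * x + b * y, 2, c(2, 4))
  px <- nsct_decompose(x, 2, c(2, 4))
  py <- nsct_decompose(y, 2, c(2, 4))
  expect_lt(max(abs(pc$lowpass - (a * px$lowpass + b * py$lowpass))), 1e-8)
  for (l in 1:2) {
    for (k in seq_along(pc$highpass[[l]])) {
      expect_lt(max(abs(pc$highpass[[l]][[k]] -
                          (a * px$highpass[[l]][[k]] + b * py$highpass[[l]][[k]]))),
                1e-8)
    }
  }
})

test_that("direction count 1 passes a scale through undirectionally", {
  x <- rand_image(32, seed = 13)
  p <- nsct_decompose(x, 2, c(1, 2))
  expect_length(p$highpass[[1]], 1L)
  expect_lt(max(abs(nsct_reconstruct(p) - x)), 1e-6)
})

test_that("configuration errors are caught", {
  x <- rand_image(32, seed = 1)
  expect_error(nsct_decompose(x, 2, c(2, 4, 8)), "one entry per level")
  expect_error(nsct_decompose(x, 2, c(2, 3)), "power of two")
  expect_error(nsct_decompose(matrix(c(1, NA, 1, 1), 2), 1, 1), "finite")
  p <- nsct_decompose(x, 2, c(2, 4))
  p$highpass[[1]][[1]] <- matrix(0, 4, 4)
  expect_error(nsct_reconstruct(p), "shape")
})
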