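test_that("octave convolution at alpha = 0 equals a dense convolution oracle", {
  set.seed(101)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  kern <- oct_kernel(8, 8, alpha_in = 0, alpha_out = 0, k = 3,
                     bias = list(h = rnorm(8)))
  got <- oct_conv(frequency_feature(x, alpha = 0), kern)
  expect_null(got$low)
  want <- oracle_conv2d_same(x, kern$W$hh, kern$b$h)
  expect_lt(max(abs(got$high - want)), 1e-5)
})

test_that("octave streams have the contracted shapes and conserve channels", {
  set.seed(102)
  x <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  kern <- oct_kernel(16, 32, alpha_in = 0.5, alpha_out = 0.5)
  xf <- frequency_feature(x[, , 1:8], avg_downsample(x)[, , 9:16], alpha = 0.5)
  y <- oct_conv(xf, kern)
  expect_equal(dim(y$high), c(32, 32, 16))
  expect_equal(dim(y$low), c(16, 16, 16))
  # channel conservation for arbitrary totals and alphas
  for (ct in c(3, 7, 16)) {
    for (a in c(0, 0.25, 0.5, 0.75)) {
      sp <- split_channels(ct, a)
      expect_equal(sum(sp), ct)
    }
  }
  # repeated application preserves the h x w / h/2 x w/2 spatial contract
  kern2 <- oct_kernel(32, 32, 0.5, 0.5)
  y2 <- oct_conv(y, kern2)
  expect_equal(dim(y2$high)[1:2], c(32, 32))
  expect_equal(dim(y2$low)[1:2], c(16, 16))
})

test_that("octave convolution is linear and maps zero to zero (zero bias)", {
  set.seed(103)
  kern <- oct_kernel(4, 6, 0.5, 0.5)
  xf <- frequency_feature(array(rnorm(8 * 8 * 2), c(8, 8, 2)),
                          array(rnorm(4 * 4 * 2), c(4, 4, 2)), 0.5)
  y1 <- oct_conv(xf, kern)
  xs <- frequency_feature(3.5 * xf$high, 3.5 * xf$low, 0.5)
  y2 <- oct_conv(xs, kern)
  expect_equal(y2$high, 3.5 * y1$high, tolerance = 1e-12)
  expect_equal(y2$low, 3.5 * y1$low, tolerance = 1e-12)
  z <- frequency_feature(xf$high * 0, xf$low * 0, 0.5)
  yz <- oct_conv(z, kern)
  expect_true(all(yz$high == 0) && all(yz$low == 0))
})

test_that("initial octave convolution establishes the split", {
  # alpha_out = 0: ordinary convolution, no low stream
  set.seed(104)
  x <- matrix(rnorm(64), 8, 8)
  k0 <- oct_kernel(1, 4, 0, 0)
  y0 <- init_oct_conv(x, k0)
  expect_null(y0$low)
  expect_lt(max(abs(y0$high - oracle_conv2d_same(x, k0$W$hh))), 1e-10)

  # shape arithmetic at alpha_out = 0.5
  k1 <- oct_kernel(1, 8, 0, 0.5)
  y1 <- init_oct_conv(array(rnorm(64 * 64), c(64, 64, 1)), k1)
  expect_equal(dim(y1$high), c(64, 64, 4))
  expect_equal(dim(y1$low), c(32, 32, 4))

  # constant input with unit 1x1 kernels: low equals high
  unit <- array(1, c(1, 1, 1, 1))
  k2 <- oct_kernel(1, 2, 0, 0.5, k = 1,
                   weights = list(hh = unit, hl = unit))
  y2 <- init_oct_conv(matrix(0.3, 6, 6), k2)
  expect_equal(unique(as.numeric(y2$high)), 0.3)
  expect_equal(unique(as.numeric(y2$low)), 0.3)

  expect_error(oct_kernel(1, 4, 0, 1.2), "alpha")
})

test_that("final octave convolution merges the streams", {
  # absent low stream: ordinary convolution of high
  set.seed(105)
  kf0 <- oct_kernel(4, 2, 0, 0)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  y <- fin_oct_conv(frequency_feature(x, alpha = 0), kf0)
  expect_lt(max(abs(y - oracle_conv2d_same(x, kf0$W$hh))), 1e-10)

  # constant streams, unit 1x1 kernels: output = a + b
  unit <- array(1, c(1, 1, 1, 1))
  kf <- oct_kernel(2, 1, 0.5, 0, k = 1,
                   weights = list(hh = unit, lh = unit))
  xf <- frequency_feature(array(0.2, c(6, 6, 1)), array(0.5, c(3, 3, 1)), 0.5)
  out <- fin_oct_conv(xf, kf)
  expect_equal(unique(as.numeric(out)), 0.7)
  # spatial size equals the high-stream input size
  expect_equal(dim(out)[1:2], c(6, 6))
})

test_that("downsample and upsample behave on constants and tiny examples", {
  expect_equal(avg_downsample(matrix(1, 2, 2)), matrix(1, 1, 1))
  expect_equal(avg_downsample(matrix(c(0, 4, 2, 6), 2, 2)), matrix(3, 1, 1))
  expect_error(avg_downsample(matrix(0, 3, 3)), "even")
  # constants are fixed points of down-then-up
  cst <- matrix(0.4, 6, 6)
  expect_equal(bilinear_upsample(avg_downsample(cst)), cst)
  expect_equal(nearest_upsample(avg_downsample(cst)), cst)
  # odd spatial size with a low stream present is rejected
  expect_error(frequency_feature(array(0, c(5, 6, 1)), array(0, c(2, 3, 1))),
               "even")
})

test_that("reported cost ratio follows the operation count, not 1/4", {
  expect_equal(oct_conv_cost_ratio(0), 1)
  expect_equal(oct_conv_cost_ratio(0.5), 7 / 16)
  expect_lt(abs(oct_conv_cost_ratio(1) - 1 / 4), 1e-12)
})
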