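test_that("blur kernels are normalized separable binomial filters", {
  expect_equal(make_blur_kernel(1), structure(matrix(1), class = c("blur_kernel", "matrix", "array")),
               ignore_attr = TRUE)
  expect_equal(unclass(make_blur_kernel(2)), matrix(0.25, 2, 2))
  expect_equal(unclass(make_blur_kernel(3)),
               matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16)
  for (size in 1:6) {
    k <- unclass(make_blur_kernel(size))
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_true(all(k >= 0))
    row <- choose(size - 1, 0:(size - 1))
    expect_equal(k, outer(row, row) / sum(outer(row, row)))
    expect_equal(k, t(k))
    expect_equal(k, k[rev(seq_len(size)), rev(seq_len(size)), drop = FALSE])
  }
  expect_error(make_blur_kernel(0), "positive")
  expect_error(make_blur_kernel(-3), "positive")
})

test_that("blur_downsample matches the nested-loop oracle and preserves DC", {
  set.seed(11)
  k3 <- make_blur_kernel(3)
  # unit impulse, computed against the explicit convolution + slicing oracle
  imp <- array(0, c(1, 1, 4, 4)); imp[1, 1, 1, 1] <- 1
  expect_equal(blur_downsample(imp, k3, 2), oracle_blur_downsample(imp, unclass(k3), 2),
               tolerance = 1e-12)
  for (rep in 1:5) {
    x <- array(rnorm(2 * 2 * 7 * 9), c(2, 2, 7, 9))
    for (stride in c(1L, 2L, 3L)) {
      expect_equal(blur_downsample(x, k3, stride),
                   oracle_blur_downsample(x, unclass(k3), stride),
                   tolerance = 1e-12)
    }
  }
  # constant map stays constant at half size (kernel sums to one)
  xc <- array(2.5, c(1, 3, 8, 8))
  y <- blur_downsample(xc, k3, 2)
  expect_equal(dim(y), c(1L, 3L, 4L, 4L))
  expect_equal(range(y), c(2.5, 2.5), tolerance = 1e-6)
  # stride 1 with the identity kernel is the identity
  expect_equal(blur_downsample(xc, make_blur_kernel(1), 1), xc)
  expect_error(blur_downsample(array(1, c(1, 1, 2, 2)), k3, 0), "stride")
})

test_that("blur_max_pool equals the brute-force oracle on random instances", {
  set.seed(12)
  k <- make_blur_kernel(3)
  for (rep in 1:20) {
    H <- sample(3:16, 1); W <- sample(3:16, 1)
    x <- array(rnorm(H * W), c(1, 1, H, W))
    expect_equal(blur_max_pool(x, k, 2), oracle_blur_max_pool(x, unclass(k), 2),
                 tolerance = 1e-10)
  }
  x <- array(rnorm(8 * 8), c(1, 1, 8, 8))
  expect_equal(blur_max_pool(x, k, 2), oracle_blur_max_pool(x, unclass(k), 2),
               tolerance = 1e-10)
  # constant in, constant out
  xc <- array(-1.2, c(2, 1, 6, 6))
  expect_equal(range(blur_max_pool(xc, k, 2)), c(-1.2, -1.2), tolerance = 1e-6)
  # monotone ramp stays monotone (max and positive-kernel filtering preserve order)
  ramp <- array(rep(seq_len(16), times = 16), c(1, 1, 16, 16))  # increases along rows
  y <- blur_max_pool(ramp, k, 2)[1, 1, , ]
  expect_true(all(apply(y, 2, function(col) all(diff(col) >= -1e-12))))
})

test_that("blur_conv composes convolution with anti-aliased downsampling", {
  set.seed(13)
  x <- array(rnorm(1 * 2 * 12 * 12), c(1, 2, 12, 12))
  w <- array(rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  b <- rnorm(3)
  # stride 1 with the size-1 blur kernel is an ordinary convolution
  expect_equal(blur_conv(x, w, b, stride = 1, kernel = make_blur_kernel(1)),
               oracle_conv2d(x, w, b), tolerance = 1e-10)
  # 192 -> 96 at stride 2
  big <- array(runif(192 * 192), c(1, 1, 192, 192))
  w1 <- array(rnorm(2 * 1 * 3 * 3), c(2, 1, 3, 3))
  expect_equal(dim(blur_conv(big, w1, stride = 2))[3:4], c(96L, 96L))
  expect_equal(dim(blur_conv(big, w1, stride = 4))[3:4], c(48L, 48L))
  expect_equal(dim(blur_conv(big, w1, stride = 8))[3:4], c(24L, 24L))
  # an all-zero filter bank gives an all-zero output of the right shape
  y0 <- blur_conv(x, array(0, dim(w)), stride = 2)
  expect_equal(dim(y0), c(1L, 3L, 6L, 6L))
  expect_true(all(y0 == 0))
  expect_error(blur_conv(x, w, b, stride = 3), "stride")
})

test_that("every anti-aliased op preserves a constant input", {
  k <- make_blur_kernel(3)
  xc <- array(0.7, c(1, 2, 8, 8))
  expect_equal(range(blur_downsample(xc, k, 2)), c(0.7, 0.7), tolerance = 1e-6)
  expect_equal(range(blur_max_pool(xc, k, 2)), c(0.7, 0.7), tolerance = 1e-6)
  # a convolution whose filters sum to 1 per output channel keeps the constant
  w <- array(0, c(2, 2, 3, 3)); w[1, 1, 2, 2] <- 1; w[2, 2, 2, 2] <- 1
  y <- blur_conv(xc, w, stride = 2)
  expect_equal(range(y), c(0.7, 0.7), tolerance = 1e-6)
})

test_that("blur pooling drifts less under a 1-pixel shift than strided max pooling", {
  set.seed(14)
  k <- make_blur_kernel(3)
  plain_max_s2 <- function(x) {
    # plain 2x2 max pooling, stride 2
    H <- dim(x)[3]; W <- dim(x)[4]
    y <- array(0, c(1, 1, H / 2, W / 2))
    for (h in seq_len(H / 2)) for (w in seq_len(W / 2)) {
      y[1, 1, h, w] <- max(x[1, 1, (2 * h - 1):(2 * h), (2 * w - 1):(2 * w)])
    }
    y
  }
  circ_shift <- function(x) {
    y <- x
    y[1, 1, , ] <- x[1, 1, c(dim(x)[3], seq_len(dim(x)[3] - 1)), ]
    y
  }
  d_blur <- d_plain <- numeric(100)
  for (i in 1:100) {
    x <- array(rnorm(32 * 32), c(1, 1, 32, 32))
    xs <- circ_shift(x)
    d_blur[i] <- sqrt(sum((blur_max_pool(x, k, 2) - blur_max_pool(xs, k, 2))^2))
    d_plain[i] <- sqrt(sum((plain_max_s2(x) - plain_max_s2(xs))^2))
  }
  expect_lt(mean(d_blur), mean(d_plain))
})
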