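test_that("DN blocks halve the spatial dims and double the channels", {
  set.seed(31)
  p <- dn_params(2L)
  x <- array(rnorm(192 * 192 * 2), c(1, 2, 192, 192))
  y <- dn_block(x, p)
  expect_equal(dim(y), c(1L, 4L, 96L, 96L))
  y2 <- dn_block(array(rnorm(24 * 24 * 2), c(1, 2, 24, 24)), p)
  expect_equal(dim(y2), c(1L, 4L, 12L, 12L))
  # zero input and zero weights give zero output of halved size
  p0 <- rapply(p, function(a) { a[] <- 0; a }, how = "replace")
  z <- dn_block(array(0, c(1, 2, 8, 8)), p0)
  expect_equal(dim(z), c(1L, 4L, 4L, 4L))
  expect_true(all(z == 0))
  expect_error(dn_block(array(0, c(1, 2, 7, 7)), p), "even")
})

test_that("pyramid blur pooling doubles the channels and matches its oracle", {
  set.seed(32)
  bins <- c(1L, 2L, 4L)
  p <- pbp_params(4L, bins)
  x <- array(rnorm(1 * 4 * 8 * 8), c(1, 4, 8, 8))
  y <- pbp_module(x, p, bins)
  # C + nbins * C/4 channels; with 3 bins of C=4: 4 + 3 = 7
  expect_equal(dim(y), c(1L, 4L + length(bins) * 1L, 8L, 8L))
  full <- pbp_module(x, pbp_params(4L), c(1L, 2L, 4L, 8L))
  expect_equal(dim(full)[2], 8L)  # 2C with the standard four bins

  # branch-by-branch explicit oracle: shared max+blur, adaptive average to the
  # bin grid, dilated conv, ReLU, nearest-neighbour upsampling
  k <- unclass(make_blur_kernel(3))
  blurred <- oracle_blur_max_pool(x, k, 1L)
  expect_equal(y[, 1:4, , ], x[, 1:4, , ], tolerance = 1e-12)
  for (bi in seq_along(bins)) {
    b <- bins[bi]
    pooled <- array(0, c(1, 4, b, b))
    for (c in 1:4) for (i in 1:b) for (j in 1:b) {
      rows <- (floor((i - 1) * 8 / b) + 1):floor(i * 8 / b)
      cols <- (floor((j - 1) * 8 / b) + 1):floor(j * 8 / b)
      pooled[1, c, i, j] <- mean(blurred[1, c, rows, cols])
    }
    conv <- oracle_conv2d(pooled, p[[bi]]$w, p[[bi]]$b, dilation = b)
    conv <- pmax(conv, 0)
    up <- array(0, c(1, 1, 8, 8))
    for (i in 1:8) for (j in 1:8) {
      up[1, 1, i, j] <- conv[1, 1, floor((i - 1) * b / 8) + 1, floor((j - 1) * b / 8) + 1]
    }
    expect_equal(y[, 4L + bi, , , drop = FALSE], up, tolerance = 1e-10)
  }

  # constant input: every branch plane is constant (DC preservation throughout)
  xc <- array(1.3, c(1, 4, 8, 8))
  yc <- pbp_module(xc, p, bins)
  for (ch in seq_len(dim(yc)[2])) {
    expect_equal(diff(range(yc[1, ch, , ])), 0, tolerance = 1e-9)
  }
})

test_that("UP blocks restore the spatial dims of the matching DN block", {
  set.seed(33)
  up <- up_params(4L, 2L)
  x <- array(rnorm(1 * 4 * 12 * 12), c(1, 4, 12, 12))
  y <- up_block(x, params = up)
  expect_equal(dim(y), c(1L, 2L, 24L, 24L))
  # zero weights give zero output of doubled size
  up0 <- rapply(up, function(a) { a[] <- 0; a }, how = "replace")
  y0 <- up_block(x, params = up0)
  expect_true(all(y0 == 0) && all(dim(y0) == c(1, 2, 24, 24)))
  # with a skip: channels concatenate before the PBP
  skip <- array(rnorm(1 * 4 * 12 * 12), c(1, 4, 12, 12))
  y2 <- up_block(x, skip = skip, params = up_params(8L, 2L))
  expect_equal(dim(y2), c(1L, 2L, 24L, 24L))
  expect_error(up_block(x, skip = array(0, c(1, 4, 6, 6)), params = up),
               "skip")
  # UP on DN output restores the original spatial dims
  dnp <- dn_params(2L)
  xin <- array(rnorm(1 * 2 * 16 * 16), c(1, 2, 16, 16))
  restored <- up_block(dn_block(xin, dnp), params = up_params(4L, 2L))
  expect_equal(dim(restored)[3:4], dim(xin)[3:4])
})

test_that("auxiliary strided features have the encoder-level sizes", {
  set.seed(34)
  ps <- lapply(1:3, function(i) list(w = array(rnorm(2 * 2 * 9), c(2, 2, 3, 3)),
                                     b = rnorm(2)))
  c1 <- array(rnorm(1 * 2 * 192 * 192), c(1, 2, 192, 192))
  a <- aux_features(c1, ps)
  expect_equal(sapply(a, function(m) dim(m)[3]), c(96L, 48L, 24L))
  c1s <- array(rnorm(1 * 2 * 64 * 64), c(1, 2, 64, 64))
  expect_equal(sapply(aux_features(c1s, ps), function(m) dim(m)[3]),
               c(32L, 16L, 8L))
  z <- aux_features(array(0, dim(c1s)),
                    lapply(ps, function(p) list(w = p$w, b = numeric(2))))
  expect_true(all(sapply(z, function(m) all(m == 0))))
})

test_that("the full network maps inputs to probabilities of identical shape", {
  cfg <- cba_config(input_size = 64, base_channels = 8)
  m <- cba_network(cfg, seed = 5)
  x <- array(runif(64 * 64), c(1, 1, 64, 64))
  p <- cba_forward(m, x)
  expect_equal(dim(p), c(1L, 1L, 64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # deterministic inference: bit-identical repeat
  expect_identical(p, cba_forward(m, x))
  expect_error(cba_forward(m, array(0, c(1, 1, 60, 60))), "divisible")
})

test_that("the encoder side sequence for a 192 input is 192/96/48/24/12", {
  cfg <- cba_config(input_size = 192, base_channels = 4)
  m <- cba_network(cfg, seed = 6)
  k <- make_blur_kernel(cfg$blur_kernel_size)
  x <- array(runif(192 * 192), c(1, 1, 192, 192))
  c1 <- blur_conv(x, m$params$c1$w, m$params$c1$b, stride = 1, kernel = k)
  sides <- dim(c1)[3]
  cur <- pmax(c1, 0)
  for (i in 1:4) {
    cur <- dn_block(cur, m$params$dn[[i]], k)
    sides <- c(sides, dim(cur)[3])
  }
  expect_equal(sides, c(192L, 96L, 48L, 24L, 12L))
  # and the decoder restores the full 192 resolution
  p <- cba_forward(m, x)
  expect_equal(dim(p)[3:4], c(192L, 192L))
})

test_that("parameter counting is exact and the default model is megaparameter-scale", {
  # single 3x3 convolution, 1 -> 8 channels with bias: 3*3*1*8 + 8 = 80
  expect_equal(count_parameters(list(init = list(w = array(0, c(8, 1, 3, 3)),
                                                 b = numeric(8)))), 80)
  expect_equal(count_parameters(list()), 0)
  m <- cba_network(cba_config(), seed = 1)
  n <- count_parameters(m)
  # documented default: ~6.6 M trainable parameters, the order of magnitude of
  # compact encoder-decoder segmenters
  expect_gt(n, 3e6)
  expect_lt(n, 9e6)
})

test_that("every parameter receives gradient from some input (no dead branches)", {
  cfg <- cba_config(input_size = 32, base_channels = 8)
  m <- cba_network(cfg, seed = 7)
  set.seed(71)
  acc <- NULL
  for (rep in 1:3) {
    x <- array(runif(2 * 32 * 32), c(2, 1, 32, 32))
    y <- array(rbinom(2 * 32 * 32, 1, 0.4), c(2, 1, 32, 32))
    Pn <- blurseg:::params_to_nodes(m$params)
    out <- blurseg:::ag_cba_forward(Pn, blurseg:::ag_param(x), cfg)
    l <- blurseg:::bce_dice_loss(out$value, y)
    blurseg:::ag_backward(out, l$grad)
    g <- blurseg:::nodes_to_grads(Pn)
    acc <- if (is.null(acc)) rapply(g, abs, how = "replace") else
      blurseg:::map2_params(function(a, b) a + abs(b), acc, g)
  }
  nonzero <- rapply(acc, function(a) any(a > 0), how = "unlist")
  expect_true(all(nonzero))
})

test_that("network autodiff agrees with numeric differentiation", {
  cfg <- cba_config(input_size = 16, base_channels = 4, depth = 2,
                    aux_strides = c(2L, 4L), pbp_bins = c(1L, 2L, 4L))
  m <- cba_network(cfg, seed = 8)
  set.seed(81)
  x <- array(runif(2 * 16 * 16), c(2, 1, 16, 16))
  y <- array(rbinom(2 * 16 * 16, 1, 0.4), c(2, 1, 16, 16))
  lossfun <- function(params) {
    mm <- m; mm$params <- params
    blurseg:::bce_dice_loss(cba_forward(mm, x), y)$loss
  }
  Pn <- blurseg:::params_to_nodes(m$params)
  out <- blurseg:::ag_cba_forward(Pn, blurseg:::ag_param(x), cfg)
  l <- blurseg:::bce_dice_loss(out$value, y)
  blurseg:::ag_backward(out, l$grad)
  G <- blurseg:::nodes_to_grads(Pn)
  paths <- list()
  walk <- function(v, p) {
    if (is.list(v)) for (i in seq_along(v)) walk(v[[i]], c(p, i))
    else paths[[length(paths) + 1]] <<- p
  }
  walk(m$params, integer(0))
  getleaf <- function(P, pth) { for (i in pth) P <- P[[i]]; P }
  setleaf <- function(P, pth, v) {
    if (length(pth) == 1) { P[[pth]] <- v; P }
    else { P[[pth[1]]] <- setleaf(P[[pth[1]]], pth[-1], v); P }
  }
  for (t in 1:12) {
    pth <- paths[[sample(length(paths), 1)]]
    leaf <- getleaf(m$params, pth)
    ci <- sample(length(leaf), 1)
    eps <- 1e-5
    lp <- leaf; lp[ci] <- lp[ci] + eps
    lm <- leaf; lm[ci] <- lm[ci] - eps
    num <- (lossfun(setleaf(m$params, pth, lp)) -
              lossfun(setleaf(m$params, pth, lm))) / (2 * eps)
    ana <- getleaf(G, pth)[ci]
    expect_equal(ana, num, tolerance = 1e-3)
  }
})
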