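# independent single-level DWT + universal soft threshold, written with
# direct per-coefficient filtering loops as a second implementation
oracle_wavelet_denoise <- function(img) {
  f <- blurseg:::wavelet_filters("bior1.3")
  n <- nrow(img); m <- ncol(img)
  off <- 2L
  ana <- function(v, filt) {
    half <- length(v) %/% 2L
    out <- numeric(half)
    for (i in seq_len(half)) {
      for (t in seq_along(filt)) {
        idx <- (2L * (i - 1L) + (t - 1L) - off) %% length(v) + 1L
        out[i] <- out[i] + filt[t] * v[idx]
      }
    }
    out
  }
  syn <- function(a, d, n) {
    y <- numeric(n)
    frl <- rev(f$rec_lo); frh <- rev(f$rec_hi)
    for (i in seq_along(a)) {
      for (t in seq_along(frl)) {
        idx <- (2L * (i - 1L) + (t - 1L) - off) %% n + 1L
        y[idx] <- y[idx] + frl[t] * a[i] + frh[t] * d[i]
      }
    }
    y
  }
  rowsL <- t(apply(img, 1, ana, filt = f$dec_lo))
  rowsH <- t(apply(img, 1, ana, filt = f$dec_hi))
  LL <- apply(rowsL, 2, ana, filt = f$dec_lo)
  HL <- apply(rowsL, 2, ana, filt = f$dec_hi)
  LH <- apply(rowsH, 2, ana, filt = f$dec_lo)
  HH <- apply(rowsH, 2, ana, filt = f$dec_hi)
  sigma <- median(abs(HH)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(img)))
  st <- function(x) sign(x) * pmax(abs(x) - thr, 0)
  LH <- st(LH); HL <- st(HL); HH <- st(HH)
  colsL <- sapply(seq_len(ncol(LL)), function(j) syn(LL[, j], HL[, j], n))
  colsH <- sapply(seq_len(ncol(LH)), function(j) syn(LH[, j], HH[, j], n))
  out <- t(sapply(seq_len(n), function(i) syn(colsL[i, ], colsH[i, ], m)))
  pmin(pmax(out, 0), 1)
}

test_that("the 2-D wavelet transform reconstructs perfectly", {
  set.seed(51)
  for (wav in c("bior1.3", "haar")) {
    x <- matrix(runif(24 * 16), 24, 16)
    b <- blurseg:::dwt2(x, wav)
    expect_equal(blurseg:::idwt2(b, wav), x, tolerance = 1e-12)
  }
})

test_that("wavelet denoising passes constants, removes noise energy, matches its oracle", {
  cimg <- matrix(0.6, 16, 16)
  expect_equal(wavelet_lowpass(cimg), cimg, tolerance = 1e-12)
  set.seed(52)
  noise <- matrix(pmin(pmax(0.5 + rnorm(64 * 64, sd = 0.1), 0), 1), 64, 64)
  den <- wavelet_lowpass(noise)
  expect_lt(var(as.vector(den)), var(as.vector(noise)))
  # seeded noisy disk, checked against the independent reimplementation
  gy <- matrix(seq_len(32), 32, 32); gx <- t(gy)
  disk <- 0.2 + 0.6 * ((gy - 16)^2 + (gx - 16)^2 <= 64)
  set.seed(53)
  noisy <- pmin(pmax(disk + rnorm(1024, sd = 0.08), 0), 1)
  expect_equal(wavelet_lowpass(noisy), oracle_wavelet_denoise(noisy),
               tolerance = 1e-10)
  expect_warning(wavelet_lowpass(matrix(0.5, 3, 3)), "support")
})

test_that("normalization converts to luminance, rescales and resizes", {
  set.seed(54)
  rgb <- array(runif(1000 * 1000 * 3), c(1000, 1000, 3))
  g <- normalize_image(rgb)
  expect_equal(dim(g), c(192L, 192L))
  expect_true(all(g >= 0 & g <= 1))
  # constant (c, c, c) maps to gray c (luminance weights sum to 1)
  cimg <- array(0.4, c(64, 64, 3))
  expect_equal(range(normalize_image(cimg, 64)), c(0.4, 0.4), tolerance = 1e-9)
  # idempotent on already-normalized input
  once <- normalize_image(rgb)
  expect_equal(normalize_image(once), once, tolerance = 1e-12)
  # 8-bit integer input is rescaled
  img8 <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_true(max(normalize_image(img8, 64)) <= 1)
  expect_error(normalize_image(numeric(0)), "empty")
})

test_that("tiling is exact and reassembly is the identity", {
  set.seed(55)
  img <- matrix(runif(1000 * 1000), 1000, 1000)
  g <- tile_image(img, patch = 250)
  expect_equal(length(g$patches), 16L)
  expect_equal(g$dims, c(4L, 4L))
  expect_equal(untile_image(g), img)
  # a patch-sized image gives exactly itself
  small <- matrix(runif(250 * 250), 250, 250)
  g1 <- tile_image(small, patch = 250)
  expect_equal(length(g1$patches), 1L)
  expect_equal(g1$patches[[1]]$image, small)
  # 500 x 750 -> 2 x 3 grid; concatenation restores the original
  rect <- matrix(runif(500 * 750), 500, 750)
  g2 <- tile_image(rect, patch = 250)
  expect_equal(length(g2$patches), 6L)
  expect_equal(untile_image(g2), rect)
  # non-divisible sides are padded and cropped back
  odd <- matrix(runif(300 * 260), 300, 260)
  g3 <- tile_image(odd, patch = 250)
  expect_equal(g3$pad, c(200L, 240L))
  expect_equal(untile_image(g3), odd)
  expect_error(tile_image(img, mask = matrix(0L, 10, 10)), "mismatch")
})

test_that("mask patches are relabelled to contiguous 1..k", {
  mask <- matrix(0L, 8, 8)
  mask[1:2, 1:2] <- 3L
  mask[6:8, 6:8] <- 7L
  g <- tile_image(matrix(0, 8, 8), mask, patch = 4)
  labs <- lapply(g$patches, function(p) sort(unique(as.vector(p$mask))))
  expect_equal(labs[[1]], c(0L, 1L))
  expect_equal(labs[[4]], c(0L, 1L))
})

test_that("augmentation streams are seeded, reproducible and label-preserving", {
  set.seed(56)
  imgs <- lapply(1:4, function(i) matrix(runif(48 * 48), 48, 48))
  msks <- lapply(1:4, function(i) random_label_map(48))
  s1 <- augment_stream(imgs, msks, seed = 9, size = 32)
  s2 <- augment_stream(imgs, msks, seed = 9, size = 32)
  d1 <- lapply(1:6, function(i) s1())
  d2 <- lapply(1:6, function(i) s2())
  expect_identical(d1, d2)
  # the stream must not disturb the global RNG
  set.seed(100); a <- runif(1)
  set.seed(100); s1(); b <- runif(1)
  expect_identical(a, b)
  # right-angle rotation permutes pixels: per-instance counts are preserved
  m <- random_label_map(32)
  r <- blurseg:::rot90k(m, 1L)
  expect_equal(tabulate(m[m > 0]), tabulate(r[r > 0]))
  # axis-aligned transforms at full size preserve the label set
  s3 <- augment_stream(list(matrix(runif(32 * 32), 32, 32)), list(m),
                       seed = 4, size = 32, free_angle_prob = 0)
  for (i in 1:8) {
    d <- s3()
    expect_equal(sort(unique(as.vector(d$mask))), sort(unique(as.vector(m))))
    expect_equal(tabulate(d$mask[d$mask > 0]), tabulate(m[m > 0]))
  }
})

test_that("a fixed-size epoch expands few base images into many crops", {
  set.seed(57)
  imgs <- lapply(1:6, function(i) matrix(runif(40 * 40), 40, 40))
  msks <- lapply(1:6, function(i) random_label_map(40))
  ep <- augment_epoch(imgs, msks, n = 37, seed = 3, size = 32)
  expect_length(ep, 37)
  expect_true(all(vapply(ep, function(d) all(dim(d$image) == c(32, 32)), TRUE)))
})
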