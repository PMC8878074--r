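# Brute-force reference implementations, deliberately written as plain nested
# loops so they stay independent of the package's vectorized kernels.

refl_idx <- function(i, n) {
  if (n == 1) return(1L)
  i <- i - 1L
  while (i < 0 || i >= n) {
    if (i < 0) i <- -i
    if (i >= n) i <- 2L * n - 2L - i
  }
  i + 1L
}

oracle_blur_downsample <- function(x, k, stride) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  K <- nrow(k); pl <- (K - 1L) %/% 2L
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  y <- array(0, c(N, C, Ho, Wo))
  for (n in 1:N) for (c in 1:C) for (ho in 1:Ho) for (wo in 1:Wo) {
    acc <- 0
    for (r in 1:K) for (s in 1:K) {
      hs <- refl_idx((ho - 1L) * stride - pl + r, H)
      ws <- refl_idx((wo - 1L) * stride - pl + s, W)
      acc <- acc + k[r, s] * x[n, c, hs, ws]
    }
    y[n, c, ho, wo] <- acc
  }
  y
}

oracle_dense_max <- function(x) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  y <- array(0, dim(x))
  for (n in 1:N) for (c in 1:C) for (h in 1:H) for (w in 1:W) {
    h1 <- min(h + 1L, H); w1 <- min(w + 1L, W)
    y[n, c, h, w] <- max(x[n, c, h, w], x[n, c, h1, w],
                         x[n, c, h, w1], x[n, c, h1, w1])
  }
  y
}

oracle_blur_max_pool <- function(x, k, stride) {
  oracle_blur_downsample(oracle_dense_max(x), k, stride)
}

oracle_conv2d <- function(x, w, b, dilation = 1L) {
  N <- dim(x)[1]; Ci <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  Co <- dim(w)[1]; k <- dim(w)[3]; p <- dilation * (k - 1L) %/% 2L
  y <- array(0, c(N, Co, H, W))
  for (n in 1:N) for (co in 1:Co) for (h in 1:H) for (ww in 1:W) {
    acc <- b[co]
    for (ci in 1:Ci) for (r in 1:k) for (s in 1:k) {
      hs <- h + dilation * (r - 1L) - p
      ws <- ww + dilation * (s - 1L) - p
      if (hs >= 1 && hs <= H && ws >= 1 && ws <= W) {
        acc <- acc + w[co, ci, r, s] * x[n, ci, hs, ws]
      }
    }
    y[n, co, h, ww] <- acc
  }
  y
}

oracle_mlp <- function(d, P) {
  # d: (N, C); two-layer perceptron with ReLU, explicit loops
  N <- nrow(d); C <- ncol(d); Hd <- ncol(P$w1)
  out <- matrix(0, N, C)
  for (n in 1:N) {
    hid <- numeric(Hd)
    for (j in 1:Hd) {
      acc <- P$b1[j]
      for (i in 1:C) acc <- acc + d[n, i] * P$w1[i, j]
      hid[j] <- max(acc, 0)
    }
    for (i in 1:C) {
      acc <- P$b2[i]
      for (j in 1:Hd) acc <- acc + hid[j] * P$w2[j, i]
      out[n, i] <- acc
    }
  }
  out
}

oracle_channel_attention <- function(x, params, k) {
  N <- dim(x)[1]; C <- dim(x)[2]
  a <- matrix(0, N, C)
  for (n in 1:N) for (c in 1:C) a[n, c] <- mean(x[n, c, , ])
  b4 <- x
  while (dim(b4)[3] > 1 || dim(b4)[4] > 1) b4 <- oracle_blur_max_pool(b4, k, 2L)
  b <- matrix(b4[, , 1, 1], N, C)
  1 / (1 + exp(-(oracle_mlp(a, params$mlp) + oracle_mlp(b, params$mlp))))
}

oracle_spatial_attention <- function(x, params, k) {
  N <- dim(x)[1]; C <- dim(x)[2]; H <- dim(x)[3]; W <- dim(x)[4]
  planes <- array(0, c(N, 2, H, W))
  for (n in 1:N) for (h in 1:H) for (w in 1:W) {
    planes[n, 1, h, w] <- mean(x[n, , h, w])
    planes[n, 2, h, w] <- max(x[n, , h, w])
  }
  planes[, 2, , ] <- oracle_blur_downsample(planes[, 2, , , drop = FALSE], k, 1L)[, 1, , ]
  z <- oracle_conv2d(planes, params$spatial$w, params$spatial$b)
  1 / (1 + exp(-z))
}

# AJI straight from its definition: explicit pairwise Jaccard table, greedy
# max matching over ground-truth labels in ascending order, unmatched
# prediction pixels added to the denominator
oracle_aji <- function(truth, pred) {
  gl <- sort(setdiff(unique(as.vector(truth)), 0))
  pl <- sort(setdiff(unique(as.vector(pred)), 0))
  if (length(gl) == 0 && length(pl) == 0) return(1)
  used <- rep(FALSE, length(pl))
  num <- 0; den <- 0
  for (gi in gl) {
    G <- truth == gi
    best_j <- 0; best_jac <- -1
    for (j in seq_along(pl)) {
      if (used[j]) next
      P <- pred == pl[j]
      inter <- sum(G & P)
      if (inter == 0) next
      jac <- inter / sum(G | P)
      if (jac > best_jac + 1e-15) { best_jac <- jac; best_j <- j }
    }
    if (best_j == 0) {
      den <- den + sum(G)
    } else {
      P <- pred == pl[best_j]
      num <- num + sum(G & P)
      den <- den + sum(G | P)
      used[best_j] <- TRUE
    }
  }
  for (j in seq_along(pl)) if (!used[j]) den <- den + sum(pred == pl[j])
  if (den == 0) 1 else num / den
}

# recursive flood fill (8-connectivity) for component counting
oracle_count_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (h in 1:H) for (w in 1:W) {
    if (!bin[h, w] || seen[h, w]) next
    count <- count + 1L
    stack <- list(c(h, w)); seen[h, w] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dh in -1:1) for (dw in -1:1) {
        nh <- cur[1] + dh; nw <- cur[2] + dw
        if (nh >= 1 && nh <= H && nw >= 1 && nw <= W &&
            bin[nh, nw] && !seen[nh, nw]) {
          seen[nh, nw] <- TRUE
          stack[[length(stack) + 1]] <- c(nh, nw)
        }
      }
    }
  }
  count
}

# random instance label map with up to max_lab blob-like instances
random_label_map <- function(side, max_lab = 5L) {
  lab <- matrix(0L, side, side)
  n <- sample.int(max_lab + 1L, 1L) - 1L
  for (i in seq_len(n)) {
    cy <- runif(1, 1, side); cx <- runif(1, 1, side)
    r <- runif(1, 1, side / 3)
    gy <- matrix(seq_len(side), side, side)
    gx <- matrix(seq_len(side), side, side, byrow = TRUE)
    hit <- (gy - cy)^2 + (gx - cx)^2 <= r^2
    lab[hit] <- i
  }
  # relabel to contiguous in case later blobs covered earlier ones entirely
  u <- sort(setdiff(unique(as.vector(lab)), 0))
  out <- matrix(0L, side, side)
  for (j in seq_along(u)) out[lab == u[j]] <- j
  out
}

# small training corpus of synthetic fluorescence scenes at network size
tiny_scene_pairs <- function(n, size = 32L, seed = 7L) {
  cfg <- scene_config(size = size, n_nuclei = c(2L, 4L),
                      radius = c(max(3, size / 10), max(4, size / 6)),
                      touching_prob = 0.1, illum_amplitude = 0.2,
                      gauss_sd = 0.02, poisson_peak = 0, seed = seed)
  lapply(seq_len(n), function(i) {
    ci <- cfg; ci$seed <- seed + i * 131L
    s <- suppressWarnings(generate_scene(ci))
    list(image = s$image, labels = s$labels)
  })
}
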