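#' Normalize an image for the network
#'
#' Converts RGB(A) input to luminance (ITU-R 601 weights 0.299/0.587/0.114,
#' alpha dropped), rescales intensities to `[0, 1]` (8- or 16-bit integer
#' ranges are detected from the value range), and resizes bilinearly to
#' `size x size`. Idempotent on already-normalized input.
#'
#' @param img Matrix (grayscale) or `H x W x {1,3,4}` array.
#' @param size Target side in pixels.
#' @return A `size x size` matrix with values in `[0, 1]`.
#' @export
normalize_image <- function(img, size = 192L) {
  d <- dim(img)
  if (is.null(d) || length(img) == 0L) stop("empty image", call. = FALSE)
  if (length(d) == 3L) {
    if (!d[3] %in% c(1L, 3L, 4L)) stop("expected 1, 3 or 4 channels", call. = FALSE)
    img <- if (d[3] == 1L) {
      img[, , 1L]
    } else {
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    }
  } else if (length(d) != 2L) {
    stop("`img` must be 2-D or 3-D", call. = FALSE)
  }
  mx <- max(img)
  if (mx > 1) img <- img / (if (mx <= 255) 255 else 65535)
  img <- pmin(pmax(img, 0), 1)
  if (nrow(img) != size || ncol(img) != size) {
    img <- as.matrix(EBImage::resize(img, w = size, h = size))
    img <- pmin(pmax(img, 0), 1)
  }
  img
}

#' Split an image (and its label map) into non-overlapping patches
#'
#' Tiles row-major into `P x P` patches; sides not divisible by `P` are
#' reflect-padded on the bottom/right (the padding is recorded in the grid so
#' [untile_image()] restores the original exactly). Instance labels inside
#' each mask patch are relabelled to a contiguous `1..k`.
#'
#' @param img Image matrix.
#' @param mask Optional instance label map of the same size.
#' @param patch Patch side `P` in pixels.
#' @return A list of class `patch_grid` with elements `size` (original H, W),
#'   `patch`, `dims` (grid rows, cols), `pad` (bottom, right) and `patches`, a
#'   row-major list of records with fields `row`, `col`, `y0`, `x0` (0-based
#'   offsets), `image` and (if given) `mask`.
#' @export
tile_image <- function(img, mask = NULL, patch = 250L) {
  if (!is.null(mask) && !all(dim(mask) == dim(img)[1:2])) {
    stop("mask / image shape mismatch", call. = FALSE)
  }
  patch <- as.integer(patch)
  H <- nrow(img); W <- ncol(img)
  pb <- (patch - H %% patch) %% patch
  pr <- (patch - W %% patch) %% patch
  xi <- pad_reflect(img, pb, pr)
  mi <- if (!is.null(mask)) pad_reflect(mask, pb, pr)
  rows <- nrow(xi) %/% patch
  cols <- ncol(xi) %/% patch
  patches <- vector("list", rows * cols)
  idx <- 0L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      idx <- idx + 1L
      ys <- (r - 1L) * patch + seq_len(patch)
      xs <- (cc - 1L) * patch + seq_len(patch)
      rec <- list(row = r, col = cc, y0 = (r - 1L) * patch, x0 = (cc - 1L) * patch,
                  image = xi[ys, xs, drop = FALSE])
      if (!is.null(mask)) rec$mask <- relabel_contiguous(mi[ys, xs, drop = FALSE])
      patches[[idx]] <- rec
    }
  }
  structure(list(size = c(H, W), patch = patch, dims = c(rows, cols),
                 pad = c(pb, pr), patches = patches),
            class = "patch_grid")
}

#' Reassemble a tiled image
#'
#' @param grid A `patch_grid` from [tile_image()].
#' @param what `"image"` or `"mask"`.
#' @return The original matrix (padding cropped away).
#' @export
untile_image <- function(grid, what = c("image", "mask")) {
  what <- match.arg(what)
  P <- grid$patch
  out <- matrix(0, grid$dims[1] * P, grid$dims[2] * P)
  for (rec in grid$patches) {
    out[rec$y0 + seq_len(P), rec$x0 + seq_len(P)] <- rec[[what]]
  }
  out[seq_len(grid$size[1]), seq_len(grid$size[2]), drop = FALSE]
}

# map arbitrary nonnegative labels to contiguous 1..k, ordered by first
# appearance in column-major scan (stable for the reassembly identity)
relabel_contiguous <- function(mask) {
  u <- unique(as.vector(mask))
  u <- sort(u[u > 0])
  if (length(u) == 0L) return(mask)
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  matrix(lut[mask + 1L], nrow(mask), ncol(mask))
}

# mirror-pad a matrix on the bottom/right (iterating if the pad exceeds the
# current size)
pad_reflect <- function(m, pb, pr) {
  while (pb > 0L) {
    step <- min(pb, nrow(m) - 1L)
    m <- rbind(m, m[nrow(m) - seq_len(step), , drop = FALSE])
    pb <- pb - step
  }
  while (pr > 0L) {
    step <- min(pr, ncol(m) - 1L)
    m <- cbind(m, m[, ncol(m) - seq_len(step), drop = FALSE])
    pr <- pr - step
  }
  m
}

# rotate by an arbitrary angle about the image centre, sampling the source
# with reflected indices so exposed corners are filled by mirroring;
# bilinear for images, nearest-neighbour for label maps
rotate_free <- function(img, angle, nearest = FALSE) {
  H <- nrow(img); W <- ncol(img)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  gy <- matrix(seq_len(H), H, W) - cy
  gx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  sy <- cos(th) * gy - sin(th) * gx + cy
  sx <- sin(th) * gy + cos(th) * gx + cx
  refl <- function(i, n) {
    i <- (i - 1) %% (2 * n - 2)
    ifelse(i >= n, 2 * n - 2 - i, i) + 1
  }
  if (nearest) {
    iy <- refl(round(sy), H); ix <- refl(round(sx), W)
    return(matrix(img[cbind(as.vector(iy), as.vector(ix))], H, W))
  }
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  g <- function(iy, ix) matrix(img[cbind(as.vector(refl(iy, H)), as.vector(refl(ix, W)))], H, W)
  (1 - fy) * (1 - fx) * g(y0, x0) + (1 - fy) * fx * g(y0, x0 + 1) +
    fy * (1 - fx) * g(y0 + 1, x0) + fy * fx * g(y0 + 1, x0 + 1)
}

rot90k <- function(m, k) {
  k <- k %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE][rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# draw one augmented (image, mask) pair using the current RNG state
augment_once <- function(img, mask, size, free_angle_prob = 0.3) {
  k <- sample(0:3, 1L)
  img <- rot90k(img, k); mask <- rot90k(mask, k)
  if (runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
                        mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE] }
  if (runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
                        mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE] }
  if (runif(1) < free_angle_prob) {
    ang <- runif(1, 0, 360)
    img <- rotate_free(img, ang)
    mask <- rotate_free(mask, ang, nearest = TRUE)
  }
  H <- nrow(img); W <- ncol(img)
  if (H < size || W < size) {  # reflect-pad small sources before cropping
    img <- pad_reflect(img, max(0L, size - H), max(0L, size - W))
    mask <- pad_reflect(mask, max(0L, size - H), max(0L, size - W))
    H <- nrow(img); W <- ncol(img)
  }
  y0 <- if (H > size) sample.int(H - size + 1L, 1L) - 1L else 0L
  x0 <- if (W > size) sample.int(W - size + 1L, 1L) - 1L else 0L
  list(image = img[y0 + seq_len(size), x0 + seq_len(size), drop = FALSE],
       mask = relabel_contiguous(mask[y0 + seq_len(size), x0 + seq_len(size), drop = FALSE]))
}

#' Seeded augmentation stream
#'
#' Returns a generator over random augmentations of a dataset: per draw, a
#' random base image gets a random right-angle rotation, horizontal/vertical
#' flips, optionally a free-angle rotation (bilinear for the image,
#' nearest-neighbour for the label map, mirror-filled corners), and a random
#' crop to the network input size. The stream keeps a private RNG state, so
#' identical seeds reproduce identical streams and the global RNG is
#' untouched.
#'
#' @param images List of image matrices.
#' @param masks List of instance label maps, parallel to `images`.
#' @param seed Integer seed of the stream.
#' @param size Crop side in pixels.
#' @param free_angle_prob Probability of applying a free-angle rotation.
#' @return A function of no arguments; each call yields
#'   `list(image, mask, index)`.
#' @export
augment_stream <- function(images, masks, seed = 1L, size = 192L,
                           free_angle_prob = 0.3) {
  if (length(images) == 0L) stop("empty dataset", call. = FALSE)
  stopifnot(length(images) == length(masks))
  rng <- NULL
  draw <- function() {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    if (is.null(rng)) set.seed(seed) else assign(".Random.seed", rng, globalenv())
    on.exit({
      rng <<- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    i <- sample.int(length(images), 1L)
    out <- augment_once(images[[i]], masks[[i]], size, free_angle_prob)
    out$index <- i
    out
  }
  draw
}

#' Fixed-size augmented epoch
#'
#' Draws `n` crops from [augment_stream()]; configured with `n = 2372` and
#' `size = 192` this mirrors the expansion of a 536-image corpus into a fixed
#' epoch of 192 x 192 training crops.
#'
#' @inheritParams augment_stream
#' @param n Number of crops to draw.
#' @return List of `n` elements, each `list(image, mask, index)`.
#' @export
augment_epoch <- function(images, masks, n, seed = 1L, size = 192L,
                          free_angle_prob = 0.3) {
  s <- augment_stream(images, masks, seed = seed, size = size,
                      free_angle_prob = free_angle_prob)
  lapply(seq_len(n), function(i) s())
}
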