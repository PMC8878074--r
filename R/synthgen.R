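#' Synthetic nuclei scene configuration
#'
#' Describes one family of synthetic microscopy scenes: elliptical nuclei
#' placed with optional touching/clustering, per-nucleus intensity jitter, a
#' smooth multiplicative illumination gradient (emulating heterogeneous
#' illumination), Gaussian read noise and optional Poisson shot noise.
#' Fluorescence mode renders bright nuclei on a dark background (grayscale);
#' histology mode renders dark stained nuclei on a bright textured background
#' with a fixed hematoxylin/eosin-like linear colour mixing (a synthetic
#' stand-in, not a stain model).
#'
#' @param size Image side in pixels.
#' @param n_nuclei Integer range `c(min, max)` of nuclei per scene.
#' @param radius Range of nucleus semi-minor axis in pixels.
#' @param eccentricity Range of the major/minor axis ratio (1 = circle).
#' @param touching_prob Probability that a nucleus is allowed to touch or
#'   slightly overlap an already placed one (labels remain distinct).
#' @param illum_amplitude Amplitude of the multiplicative illumination field
#'   (0 disables it).
#' @param gauss_sd Standard deviation of additive Gaussian noise.
#' @param poisson_peak Photon count at intensity 1 for Poisson shot noise
#'   (0 disables it).
#' @param mode `"fluorescence"` or `"histology"`.
#' @param seed Integer seed used by [generate_scene()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(size = 256L, n_nuclei = c(6L, 14L), radius = c(6L, 14L),
                         eccentricity = c(1, 1.8), touching_prob = 0.2,
                         illum_amplitude = 0.3, gauss_sd = 0.03,
                         poisson_peak = 200, mode = c("fluorescence", "histology"),
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(length(n_nuclei) == 2L, n_nuclei[1] <= n_nuclei[2], n_nuclei[1] >= 0,
            length(radius) == 2L, radius[1] <= radius[2], radius[1] > 0,
            eccentricity[1] >= 1, eccentricity[1] <= eccentricity[2],
            touching_prob >= 0, touching_prob <= 1)
  structure(list(size = as.integer(size), n_nuclei = as.integer(n_nuclei),
                 radius = radius, eccentricity = eccentricity,
                 touching_prob = touching_prob, illum_amplitude = illum_amplitude,
                 gauss_sd = gauss_sd, poisson_peak = poisson_peak,
                 mode = mode, seed = as.integer(seed)),
            class = "scene_config")
}

# squared normalized ellipse distance of every pixel to one nucleus
ellipse_dist2 <- function(size, cy, cx, ry, rx, theta) {
  gy <- matrix(seq_len(size), size, size) - cy
  gx <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- cos(theta) * gy + sin(theta) * gx
  v <- -sin(theta) * gy + cos(theta) * gx
  (u / ry)^2 + (v / rx)^2
}

#' Generate one synthetic nuclei scene
#'
#' Places random ellipses by rejection sampling (respecting the configured
#' touching probability), renders them with per-nucleus intensity jitter,
#' applies a smooth multiplicative illumination field and noise, and returns
#' the image together with an exact instance label map (touching nuclei keep
#' distinct labels; overlap pixels go to the nucleus with the smaller
#' normalized ellipse distance). The generator is fully determined by
#' `config$seed` and leaves the global RNG untouched.
#'
#' @param config A [scene_config()].
#' @return List with `image` (matrix in `[0, 1]`, or `H x W x 3` array in
#'   histology mode), `labels` (integer instance label map) and `n_placed`;
#'   if the requested count could not be packed, `n_placed` is smaller and a
#'   warning is attached as attribute `packing_warning`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(config$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))

  S <- config$size
  n_target <- if (config$n_nuclei[1] == config$n_nuclei[2]) config$n_nuclei[1] else
    sample(config$n_nuclei[1]:config$n_nuclei[2], 1L)
  labels <- matrix(0L, S, S)
  dist_best <- matrix(Inf, S, S)
  intensity <- numeric(n_target)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 60L * max(n_target, 1L)
  centres <- matrix(0, 0, 2)
  radii <- numeric(0)
  while (placed < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ry <- runif(1, config$radius[1], config$radius[2])
    ecc <- runif(1, config$eccentricity[1], config$eccentricity[2])
    rx <- ry * ecc
    rmax <- max(ry, rx)
    cy <- runif(1, 1 + rmax, S - rmax)
    cx <- runif(1, 1 + rmax, S - rmax)
    if (S <= 2 * rmax + 2) { cy <- runif(1, 1, S); cx <- runif(1, 1, S) }
    touch_ok <- runif(1) < config$touching_prob
    if (placed > 0L) {
      dc <- sqrt((centres[, 1] - cy)^2 + (centres[, 2] - cx)^2)
      sep <- radii + rmax
      if (any(dc < (if (touch_ok) 0.75 else 1.15) * sep)) next
    }
    theta <- runif(1, 0, pi)
    d2 <- ellipse_dist2(S, cy, cx, ry, rx, theta)
    inside <- d2 <= 1
    if (!any(inside)) next
    placed <- placed + 1L
    take <- inside & d2 < dist_best
    labels[take] <- placed
    dist_best[take] <- d2[take]
    intensity[placed] <- runif(1, 0.55, 0.95)
    centres <- rbind(centres, c(cy, cx))
    radii <- c(radii, rmax)
  }
  labels <- relabel_contiguous(labels)

  fg <- matrix(0, S, S)
  for (i in seq_len(placed)) fg[labels == i] <- intensity[i]

  if (config$mode == "fluorescence") {
    img <- 0.08 + fg
  } else {
    img <- 0.85 - 0.6 * (fg > 0)  # intensity plane; colour mixed below
  }
  if (config$illum_amplitude > 0) {
    gy <- matrix(seq_len(S) / S, S, S)
    gx <- matrix(seq_len(S) / S, S, S, byrow = TRUE)
    a <- runif(3, -1, 1)
    field <- a[1] * gy + a[2] * gx + a[3] * gy * gx
    field <- field - min(field)
    if (max(field) > 0) field <- field / max(field)
    img <- img * (1 - config$illum_amplitude / 2 + config$illum_amplitude * field)
  }
  if (config$poisson_peak > 0) {
    img <- matrix(rpois(S * S, pmax(img, 0) * config$poisson_peak), S, S) /
      config$poisson_peak
  }
  if (config$gauss_sd > 0) img <- img + rnorm(S * S, sd = config$gauss_sd)
  img <- pmin(pmax(img, 0), 1)

  if (config$mode == "histology") {
    # fixed hematoxylin/eosin-like mixing: nuclei bluish-purple, background pink
    w <- (1 - img)  # stain density
    rgb <- array(0, c(S, S, 3L))
    rgb[, , 1] <- pmin(pmax(0.93 - 0.55 * w, 0), 1)
    rgb[, , 2] <- pmin(pmax(0.80 - 0.62 * w, 0), 1)
    rgb[, , 3] <- pmin(pmax(0.90 - 0.25 * w, 0), 1)
    img <- rgb
  }

  out <- list(image = img, labels = labels, n_placed = placed)
  if (placed < n_target) {
    warning(sprintf("packed %d of %d nuclei", placed, n_target))
    attr(out, "packing_warning") <- TRUE
  }
  out
}

#' Generate a synthetic corpus on disk
#'
#' Writes `n` scenes as 8-bit PNG images (grayscale or RGB), 16-bit TIFF
#' instance label maps, and a manifest CSV. Per-scene seeds are derived
#' deterministically from `config$seed`, so the same configuration always
#' produces a byte-identical corpus.
#'
#' @param config A [scene_config()]; its `seed` is the master seed.
#' @param n Number of scenes (>= 1).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame (columns `image`, `labels`,
#'   `seed`, `n_nuclei`).
#' @export
generate_dataset <- function(config, n, out_dir) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- config
    ci$seed <- derive_seed(config$seed, i)
    sc <- suppressWarnings(generate_scene(ci))
    img_file <- sprintf("image_%04d.png", i)
    lab_file <- sprintf("labels_%04d.tif", i)
    png::writePNG(sc$image, file.path(out_dir, img_file))
    tiff::writeTIFF(sc$labels / 65535, file.path(out_dir, lab_file),
                    bits.per.sample = 16L)
    rows[[i]] <- data.frame(image = img_file, labels = lab_file,
                            seed = ci$seed, n_nuclei = sc$n_placed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

# deterministic per-item seed below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 16807) %% 2147483629)
}

# in-memory corpus: list of list(image, labels)
generate_scenes <- function(config, n) {
  lapply(seq_len(n), function(i) {
    ci <- config
    ci$seed <- derive_seed(config$seed, i)
    suppressWarnings(generate_scene(ci))
  })
}
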