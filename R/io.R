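#' Read an image file
#'
#' Reads PNG or TIFF into a matrix (grayscale) or `H x W x C` array with
#' values in `[0, 1]`.
#'
#' @param path File path ending in .png, .tif or .tiff.
#' @return Numeric matrix or array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1L]
  img
}

#' Read an instance label map
#'
#' Accepts either a single integer label image (16-bit TIFF/PNG where pixel
#' value = instance label) or a Data Science Bowl-style directory containing
#' `masks/` with one binary PNG per instance (the union is taken; overlapping
#' instance masks are an error).
#'
#' @param path Label image file or DSB-style sample directory.
#' @return Integer matrix, 0 = background, labels contiguous `1..L`.
#' @export
read_label_map <- function(path) {
  if (dir.exists(path)) {
    mask_dir <- file.path(path, "masks")
    if (!dir.exists(mask_dir)) stop("no masks/ directory in ", path, call. = FALSE)
    files <- sort(list.files(mask_dir, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no mask PNGs in ", mask_dir, call. = FALSE)
    lab <- NULL
    for (i in seq_along(files)) {
      m <- read_image(files[i])
      if (length(dim(m)) == 3L) m <- m[, , 1L]
      if (is.null(lab)) lab <- matrix(0L, nrow(m), ncol(m))
      hit <- m > 0.5
      if (any(lab[hit] != 0L)) stop("overlapping instance masks in ", path, call. = FALSE)
      lab[hit] <- i
    }
    return(relabel_contiguous(lab))
  }
  img <- read_image(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  # any positive integer scale works: labels are relabelled to contiguous 1..L
  relabel_contiguous(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
}

#' Load an image/label corpus from a directory
#'
#' Reads a corpus written by [generate_dataset()] (a `manifest.csv` pairing
#' image and label files), or pairs `image_*` with `labels_*` files by shared
#' suffix when no manifest is present.
#'
#' @param dir Corpus directory.
#' @return List of `list(image, labels, id)` entries.
#' @export
load_corpus <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  manifest <- file.path(dir, "manifest.csv")
  if (file.exists(manifest)) {
    mf <- read.csv(manifest, stringsAsFactors = FALSE)
    return(lapply(seq_len(nrow(mf)), function(i) {
      list(image = read_image(file.path(dir, mf$image[i])),
           labels = read_label_map(file.path(dir, mf$labels[i])),
           id = tools::file_path_sans_ext(mf$image[i]))
    }))
  }
  imgs <- sort(list.files(dir, pattern = "^image_.*\\.(png|tif|tiff)$"))
  labs <- sort(list.files(dir, pattern = "^labels_.*\\.(png|tif|tiff)$"))
  if (length(imgs) == 0L || length(imgs) != length(labs)) {
    stop("cannot pair images with label maps in ", dir, call. = FALSE)
  }
  lapply(seq_along(imgs), function(i) {
    list(image = read_image(file.path(dir, imgs[i])),
         labels = read_label_map(file.path(dir, labs[i])),
         id = tools::file_path_sans_ext(imgs[i]))
  })
}

#' Save / load a trained model
#'
#' The parameter arrays are serialized with R's native format; the
#' architecture configuration is additionally written as a YAML side file so
#' checkpoints are self-describing.
#'
#' @param model A [cba_network()].
#' @param path Checkpoint path (`.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cba_network"))
  saveRDS(model, path)
  yaml::write_yaml(unclass(model$config),
                   paste0(tools::file_path_sans_ext(path), ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cba_network"))
  model
}
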