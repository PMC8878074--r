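#' Segment nuclei in an image
#'
#' Normalizes the input to grayscale `[0, 1]` (without resizing), runs the
#' network — tiling images larger than the network input size into
#' reflect-padded patches and stitching the probability maps back together —
#' and converts the stitched probability map to an instance label map.
#' Deterministic: the same model and image always give identical output.
#'
#' @param model A [cba_network()].
#' @param img Image matrix or `H x W x C` array; sides need not match the
#'   network input size.
#' @param threshold Foreground probability threshold.
#' @param min_size Minimum instance size in pixels.
#' @param denoise Apply [wavelet_lowpass()] before the forward pass.
#' @return List with `prob` (probability matrix, same size as `img`) and
#'   `labels` (instance label map).
#' @export
predict_nuclei <- function(model, img, threshold = 0.5, min_size = 4L,
                           denoise = FALSE) {
  stopifnot(inherits(model, "cba_network"))
  if (is.null(dim(img))) stop("`img` must be an image matrix or array", call. = FALSE)
  d <- dim(img)
  if (length(d) == 3L) {  # luminance only; the original size is kept
    img <- if (d[3] == 1L) img[, , 1L] else
      0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  }
  mx <- max(img)
  if (mx > 1) img <- img / (if (mx <= 255) 255 else 65535)
  img <- pmin(pmax(img, 0), 1)
  if (denoise) img <- wavelet_lowpass(img)
  S <- model$config$input_size
  H <- nrow(img); W <- ncol(img)
  if (H == S && W == S) {
    prob <- cba_forward(model, img)[1, 1, , ]
  } else {
    grid <- tile_image(img, mask = NULL, patch = S)
    P <- S
    full <- matrix(0, grid$dims[1] * P, grid$dims[2] * P)
    for (rec in grid$patches) {
      full[rec$y0 + seq_len(P), rec$x0 + seq_len(P)] <-
        cba_forward(model, rec$image)[1, 1, , ]
    }
    prob <- full[seq_len(H), seq_len(W), drop = FALSE]
  }
  list(prob = prob, labels = instances_from_probability(prob, threshold, min_size))
}

#' Evaluate predicted label maps against ground truth
#'
#' Pairs prediction and truth files by base name, computes per-image and
#' aggregate metrics, and optionally writes them as CSV. Unmatched files are
#' reported in the `unmatched` attribute and skipped.
#'
#' @param pred_dir Directory of predicted label maps (PNG/TIFF).
#' @param truth_dir Directory of ground-truth label maps, or a corpus
#'   directory written by [generate_dataset()] (its `labels_*` files are
#'   used).
#' @param out_csv Optional path for the metrics CSV.
#' @return The [metrics_table()] data frame; attribute `unmatched` lists
#'   files without a partner (empty character vector if none).
#' @export
evaluate_dirs <- function(pred_dir, truth_dir, out_csv = NULL) {
  list_labels <- function(dir) {
    f <- list.files(dir, pattern = "\\.(png|tif|tiff)$")
    f <- f[!grepl("^image_", f)]
    names(f) <- sub("^labels_", "", tools::file_path_sans_ext(f))
    f
  }
  pf <- list_labels(pred_dir)
  tf <- list_labels(truth_dir)
  common <- intersect(names(pf), names(tf))
  unmatched <- c(setdiff(names(pf), common), setdiff(names(tf), common))
  if (length(common) == 0L) stop("no matching label files", call. = FALSE)
  common <- sort(common)
  truths <- lapply(common, function(k) read_label_map(file.path(truth_dir, tf[[k]])))
  preds <- lapply(common, function(k) read_label_map(file.path(pred_dir, pf[[k]])))
  df <- metrics_table(truths, preds, ids = common)
  if (!is.null(out_csv)) write.csv(df, out_csv, row.names = FALSE)
  attr(df, "unmatched") <- unmatched
  df
}
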