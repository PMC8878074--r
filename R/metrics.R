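#' Dice similarity coefficient
#'
#' `DSC = 2|A intersect B| / (|A| + |B|)`, the standard pixel-overlap score in
#' `[0, 1]`. Defined as 1 when both masks are empty.
#'
#' @param a,b Binary masks (logical or 0/1 numeric) of the same shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch", call. = FALSE)
  a <- a > 0; b <- b > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Pixel-level confusion counts
#'
#' @param pred,truth Binary masks of the same shape.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn` summing to the
#'   pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("shape mismatch", call. = FALSE)
  p <- pred > 0; t <- truth > 0
  list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t))
}

#' Pixel-level precision, recall and F1
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, F1 their harmonic mean.
#' Conventions for degenerate cases: precision 1 with no predicted positives,
#' recall 1 with no true positives, F1 0 when precision + recall = 0.
#'
#' @inheritParams confusion_counts
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
pixel_prf <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  precision <- if (cc$tp + cc$fp == 0) 1 else cc$tp / (cc$tp + cc$fp)
  recall <- if (cc$tp + cc$fn == 0) 1 else cc$tp / (cc$tp + cc$fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Aggregated Jaccard index
#'
#' Object-level segmentation score. Ground-truth nuclei are visited in
#' ascending label order; each is matched to the not-yet-used predicted
#' nucleus with the maximal Jaccard index (ties broken by the lowest predicted
#' label). Matched pairs contribute their intersection to the numerator and
#' their union to the denominator; a ground-truth nucleus with no overlapping
#' candidate contributes its own area to the denominator; finally, the pixel
#' counts of all unmatched predicted nuclei are added to the denominator, so
#' both over- and under-segmentation decrease the score. The matching is
#' one-to-one (each predicted nucleus is consumed by at most one ground-truth
#' nucleus).
#'
#' @param truth,pred Instance label maps of the same shape (integer matrices,
#'   0 = background). Labels need not be contiguous.
#' @return Numeric scalar in `[0, 1]`; 1 by convention when both maps are
#'   empty. Note the score is not symmetric in its arguments.
#' @export
aji <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred))) stop("shape mismatch", call. = FALSE)
  truth <- relabel_contiguous(truth)
  pred <- relabel_contiguous(pred)
  L <- max(truth); M <- max(pred)
  if (L == 0 && M == 0) return(1)
  area_g <- tabulate(truth[truth > 0], nbins = max(L, 1L))
  area_p <- tabulate(pred[pred > 0], nbins = max(M, 1L))
  # contingency of overlapping (truth, pred) label pairs
  both <- truth > 0 & pred > 0
  inter <- matrix(0L, nrow = L, ncol = max(M, 1L))
  if (any(both) && M > 0) {
    key <- (truth[both] - 1L) * M + pred[both]
    tab <- tabulate(key, nbins = L * M)
    inter <- matrix(tab, nrow = L, ncol = M, byrow = TRUE)
  }
  used <- logical(M)
  num <- 0; den <- 0
  for (i in seq_len(L)) {
    cand <- if (M > 0) which(inter[i, ] > 0 & !used) else integer(0)
    if (length(cand) == 0L) {
      den <- den + area_g[i]
      next
    }
    jac <- inter[i, cand] / (area_g[i] + area_p[cand] - inter[i, cand])
    j <- cand[which.max(jac)]  # which.max takes the first (lowest label) tie
    num <- num + inter[i, j]
    den <- den + area_g[i] + area_p[j] - inter[i, j]
    used[j] <- TRUE
  }
  if (M > 0) den <- den + sum(area_p[!used])
  if (den == 0) return(1)
  num / den
}

#' Instance labels from a probability map
#'
#' Thresholds a semantic probability map, removes connected components
#' smaller than `min_size` pixels, and labels the remaining 8-connected
#' components `1..L` in raster order of their first pixel.
#'
#' @param prob Matrix of probabilities in `[0, 1]`.
#' @param threshold Foreground threshold (pixels strictly above it are kept).
#' @param min_size Minimum component size in pixels.
#' @return Integer instance label map.
#' @export
instances_from_probability <- function(prob, threshold = 0.5, min_size = 4L) {
  bin <- matrix(as.integer(prob > threshold), nrow(prob), ncol(prob))
  lab <- cpp_label8(bin)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    drop <- which(sizes < min_size)
    if (length(drop) > 0L) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_by_raster(lab)
    }
  }
  lab
}

# contiguous relabelling in raster (row-major) order of each component's
# first pixel
relabel_by_raster <- function(lab) {
  tl <- t(lab)
  u <- unique(tl[tl > 0])
  if (length(u) == 0L) return(lab)
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- seq_along(u)
  matrix(lut[lab + 1L], nrow(lab), ncol(lab))
}

#' Per-image segmentation metrics
#'
#' Pixel-level Dice, F1, recall and precision on the binarized foreground
#' plus the object-level aggregated Jaccard index.
#'
#' @param truth,pred Instance label maps of the same shape.
#' @return Named numeric vector `c(dsc, f1, recall, precision, aji)`.
#' @export
metrics_report <- function(truth, pred) {
  prf <- pixel_prf(pred, truth)
  c(dsc = dice(pred > 0, truth > 0),
    f1 = unname(prf["f1"]),
    recall = unname(prf["recall"]),
    precision = unname(prf["precision"]),
    aji = aji(truth, pred))
}

#' Metrics over a set of image pairs
#'
#' @param truths,preds Parallel lists of instance label maps.
#' @param ids Optional image identifiers.
#' @param pooled If `TRUE`, also append a row with pixel metrics computed on
#'   the pooled pixels of the whole set (AJI stays the per-image mean).
#' @return Data frame with one row per image and a final `aggregate` row
#'   holding the unweighted per-image means; columns
#'   `image, dsc, f1, recall, precision, aji`.
#' @export
metrics_table <- function(truths, preds, ids = NULL, pooled = FALSE) {
  stopifnot(length(truths) == length(preds))
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(truths))
  rows <- t(mapply(function(tr, pr) metrics_report(tr, pr), truths, preds))
  df <- data.frame(image = ids, rows, stringsAsFactors = FALSE)
  agg <- data.frame(image = "aggregate", t(colMeans(rows)), stringsAsFactors = FALSE)
  df <- rbind(df, agg)
  if (pooled) {
    tr <- do.call(cbind, lapply(truths, function(m) m > 0))
    pr <- do.call(cbind, lapply(preds, function(m) m > 0))
    prf <- pixel_prf(pr, tr)
    df <- rbind(df, data.frame(
      image = "pooled_pixels", dsc = dice(pr, tr), f1 = unname(prf["f1"]),
      recall = unname(prf["recall"]), precision = unname(prf["precision"]),
      aji = mean(rows[, "aji"]), stringsAsFactors = FALSE))
  }
  rownames(df) <- NULL
  df
}
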