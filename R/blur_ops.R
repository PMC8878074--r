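#' Normalized binomial blur kernel
#'
#' Builds the separable low-pass filter used by every anti-aliased operation
#' in the package: the outer product of a binomial coefficient row
#' `choose(size - 1, 0:(size - 1))` with itself, normalized to sum to one.
#' Size 1 is the identity filter; size 3 gives the classic
#' `[1,2,1]/4` x `[1,2,1]/4` tent.
#'
#' @param size Positive integer, kernel side length in pixels.
#' @return A `size x size` numeric matrix of class `blur_kernel` whose entries
#'   are nonnegative and sum to 1.
#' @examples
#' make_blur_kernel(3) * 16
#' @export
make_blur_kernel <- function(size = 3L) {
  if (length(size) != 1L || is.na(size) || size < 1 || size != round(size)) {
    stop("`size` must be a positive integer", call. = FALSE)
  }
  size <- as.integer(size)
  row <- choose(size - 1L, seq_len(size) - 1L)
  k <- outer(row, row)
  k <- k / sum(k)
  class(k) <- c("blur_kernel", class(k))
  k
}

#' Coerce to a 4-axis feature map
#'
#' Accepts a matrix (one image), a 3-D array interpreted as
#' `(channel, height, width)`, or a 4-D `(batch, channel, height, width)`
#' array, and returns the 4-D form.
#'
#' @param x Numeric matrix or array.
#' @return Numeric array with `dim = c(batch, channel, height, width)`.
#' @export
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 4L) {
    stop("expected a matrix or a 3-/4-axis array", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("feature map entries must be finite", call. = FALSE)
  if (length(d) == 2L) {
    x <- array(x, dim = c(1L, 1L, d))
  } else if (length(d) == 3L) {
    y <- array(0, dim = c(1L, d))
    y[1L, , , ] <- x
    x <- y
  }
  if (any(dim(x)[3:4] < 1L)) stop("spatial dimensions must be >= 1", call. = FALSE)
  x
}

check_stride <- function(stride) {
  if (length(stride) != 1L || is.na(stride) || stride < 1 || stride != round(stride)) {
    stop("`stride` must be a positive integer", call. = FALSE)
  }
  as.integer(stride)
}

#' Anti-aliased downsampling
#'
#' Convolves each channel with a normalized low-pass kernel (reflect padding,
#' so the filtered map keeps the input size) and then subsamples every
#' `stride` pixels starting at index 0. Output spatial dims are
#' `ceiling(input / stride)`. Because the kernel sums to one, a constant input
#' maps to the same constant.
#'
#' @param x Feature map (see [as_feature_map()]).
#' @param kernel Blur kernel from [make_blur_kernel()].
#' @param stride Positive integer subsampling factor.
#' @return Feature map of size `ceiling(c(H, W) / stride)`.
#' @export
blur_downsample <- function(x, kernel = make_blur_kernel(3L), stride = 2L) {
  x <- as_feature_map(x)
  stride <- check_stride(stride)
  cpp_blurdown_fwd(x, unclass(kernel), stride)
}

#' Anti-aliased max pooling (blur pooling)
#'
#' Max pooling decomposed into dense (stride-1) 2x2 max evaluation, low-pass
#' filtering, and naive subsampling. Inserting the low-pass filter between the
#' dense max and the subsampling suppresses aliasing, so small shifts of the
#' input perturb the pooled features less than with plain strided max pooling.
#'
#' @inheritParams blur_downsample
#' @return Feature map of size `ceiling(c(H, W) / stride)`.
#' @export
blur_max_pool <- function(x, kernel = make_blur_kernel(3L), stride = 2L) {
  x <- as_feature_map(x)
  stride <- check_stride(stride)
  m <- cpp_maxdense_fwd(x)$y
  cpp_blurdown_fwd(m, unclass(kernel), stride)
}

#' Anti-aliased strided convolution (blur convolution)
#'
#' A learned convolution applied at stride 1 (zero padding, "same" output),
#' followed by anti-aliased downsampling at the requested stride. For
#' `stride = 1` the low-pass filter is still applied, without subsampling, so
#' the stride-1 blur convolution is an ordinary convolution followed by a
#' fixed smoothing.
#'
#' @param x Feature map.
#' @param weights Filter bank, array `(out_channels, in_channels, k, k)` with
#'   odd `k`.
#' @param bias Numeric vector of length `out_channels` (default zeros).
#' @param stride One of 1, 2, 4, 8.
#' @param kernel Blur kernel used for the anti-aliased downsampling step.
#' @param dilation Tap spacing of the learned convolution.
#' @return Feature map with `out_channels` channels and spatial dims
#'   `ceiling(c(H, W) / stride)`.
#' @export
blur_conv <- function(x, weights, bias = NULL, stride = 1L,
                      kernel = make_blur_kernel(3L), dilation = 1L) {
  x <- as_feature_map(x)
  if (!stride %in% c(1L, 2L, 4L, 8L)) {
    stop("`stride` must be one of 1, 2, 4, 8", call. = FALSE)
  }
  wd <- dim(weights)
  if (length(wd) != 4L || wd[3] != wd[4] || wd[3] %% 2L == 0L) {
    stop("`weights` must be (out, in, k, k) with odd k", call. = FALSE)
  }
  if (wd[2] != dim(x)[2]) stop("channel mismatch between `x` and `weights`", call. = FALSE)
  if (is.null(bias)) bias <- numeric(wd[1])
  y <- cpp_conv2d_fwd(x, weights, bias, as.integer(dilation))
  cpp_blurdown_fwd(y, unclass(kernel), as.integer(stride))
}
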