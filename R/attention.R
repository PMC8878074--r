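#' Parameters for a blur attention module
#'
#' Allocates the learnable weights of the channel/spatial blur attention unit:
#' a two-layer perceptron with channel reduction ratio `mlp_ratio` (shared by
#' the average-pooled and blur-pooled channel descriptors) and a single 3x3
#' convolution over the two concatenated spatial descriptor planes. Weights
#' are He-initialized from the current RNG state; biases start at zero.
#'
#' @param channels Number of channels of the feature maps the module will see.
#' @param mlp_ratio Channel reduction ratio of the shared perceptron
#'   (hidden width = `max(1, channels / mlp_ratio)`).
#' @return A list with components `mlp` (`w1`, `b1`, `w2`, `b2`) and
#'   `spatial` (`w`, `b`).
#' @export
attention_params <- function(channels, mlp_ratio = 8L) {
  hidden <- max(1L, as.integer(round(channels / mlp_ratio)))
  list(
    mlp = list(
      w1 = matrix(rnorm(channels * hidden, sd = sqrt(2 / channels)), channels, hidden),
      b1 = numeric(hidden),
      w2 = matrix(rnorm(hidden * channels, sd = sqrt(2 / hidden)), hidden, channels),
      b2 = numeric(channels)
    ),
    spatial = list(
      w = array(rnorm(1L * 2L * 3L * 3L, sd = sqrt(2 / (2 * 9))), c(1L, 2L, 3L, 3L)),
      b = numeric(1L)
    )
  )
}

# shared MLP applied to an (N, C) descriptor matrix (node form)
ag_att_mlp <- function(d, P) {
  ag_linear(ag_relu_mat(ag_linear(d, P$w1, P$b1)), P$w2, P$b2)
}

# channel blur attention as tape nodes; returns an (N, C) matrix node of
# weights in (0, 1)
ag_channel_attention <- function(x, P, kernel) {
  a <- ag_gap(x)
  b <- x
  while (dim(b$value)[3] > 1L || dim(b$value)[4] > 1L) {
    b <- ag_blurdown(ag_maxdense(b), kernel, 2L)
  }
  b <- ag_squeeze2(b)
  ag_sigmoid_mat(ag_add(ag_att_mlp(a, P$mlp), ag_att_mlp(b, P$mlp)))
}

# spatial blur attention as tape nodes; returns an (N, 1, H, W) node
ag_spatial_attention <- function(x, P, kernel) {
  a <- ag_chanmean(x)
  b <- ag_blurdown(ag_chanmax(x), kernel, 1L)
  ag_sigmoid(ag_conv2d(ag_concat(list(a, b)), P$spatial$w, P$spatial$b))
}

# Both attention maps are computed from the same input map and applied in
# channel-then-spatial order (the printed form of the composition; unlike the
# sequential CBAM convention, the spatial unit does not see the
# channel-refined features).
ag_blur_attention <- function(x, P, kernel) {
  mcb <- ag_channel_attention(x, P, kernel)
  msb <- ag_spatial_attention(x, P, kernel)
  ag_mul_spat(ag_mul_chan(x, mcb), msb)
}

#' Channel blur attention
#'
#' Per-channel attention weights obtained from two global descriptors of the
#' input: the spatial average of each channel, and the result of repeatedly
#' blur-max-pooling each channel down to a single pixel. Both descriptors pass
#' through the same two-layer perceptron; the sum of the two outputs is mapped
#' through a logistic sigmoid.
#'
#' @param x Feature map `(batch, channel, height, width)`.
#' @param params Parameters from [attention_params()].
#' @param kernel Blur kernel for the blur-pooled descriptor path.
#' @return Array `(batch, channel, 1, 1)` of weights in (0, 1).
#' @export
channel_blur_attention <- function(x, params, kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  if (dim(x)[2] != nrow(params$mlp$w1)) {
    stop("channel count does not match `params`", call. = FALSE)
  }
  m <- ag_channel_attention(ag_param(x), params_to_nodes(params), kernel)$value
  array(m, dim = c(dim(x)[1:2], 1L, 1L))
}

#' Spatial blur attention
#'
#' Per-pixel attention weights from two channel-pooled planes: the mean over
#' channels, and the max over channels followed by one pass of the spatial
#' low-pass filter (blur pooling without subsampling). The two planes are
#' concatenated and filtered by a learned 3x3 convolution, then mapped through
#' a sigmoid.
#'
#' @inheritParams channel_blur_attention
#' @return Array `(batch, 1, height, width)` of weights in (0, 1).
#' @export
spatial_blur_attention <- function(x, params, kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  if (any(dim(x)[3:4] < 3L)) {
    stop("spatial dims must be at least 3x3", call. = FALSE)
  }
  ag_spatial_attention(ag_param(x), params_to_nodes(params), kernel)$value
}

#' Blur attention module
#'
#' Applies channel blur attention and then spatial blur attention to a feature
#' map: `F_out = (M_CB * F) * M_SB` with broadcasting, where both attention
#' maps have entries in (0, 1). The output has the same shape as the input and
#' is elementwise no larger in magnitude.
#'
#' @inheritParams channel_blur_attention
#' @return Feature map of the same shape as `x`.
#' @export
blur_attention_module <- function(x, params, kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  ag_blur_attention(ag_param(x), params_to_nodes(params), kernel)$value
}
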