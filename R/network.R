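#' Network configuration
#'
#' Pins every architecture hyperparameter in one place. The encoder halves the
#' spatial side `depth` times (192 -> 96 -> 48 -> 24 -> 12 for the defaults)
#' while doubling the channel count, the decoder mirrors it with transpose
#' convolutions, and auxiliary anti-aliased convolutions at strides 2/4/8 feed
#' extra features into the skip connections.
#'
#' @param input_size Input image side in pixels; must be divisible by
#'   `2^depth`.
#' @param input_channels Number of input channels (1 = grayscale).
#' @param base_channels Channel count after the stem convolution; doubled at
#'   every downsampling block.
#' @param depth Number of DN/UP block pairs.
#' @param blur_kernel_size Side of the binomial low-pass kernel used by every
#'   anti-aliased operation.
#' @param mlp_ratio Channel reduction ratio inside the attention perceptrons.
#' @param pbp_bins Grid sizes of the pyramid blur pooling branches, strictly
#'   increasing.
#' @param aux_strides Strides of the auxiliary skip convolutions (fixed
#'   2, 4, 8 for depth 4).
#' @return An object of class `cba_config`.
#' @export
cba_config <- function(input_size = 192L, input_channels = 1L,
                       base_channels = 24L, depth = 4L,
                       blur_kernel_size = 3L, mlp_ratio = 8L,
                       pbp_bins = c(1L, 2L, 4L, 8L),
                       aux_strides = c(2L, 4L, 8L)) {
  input_size <- as.integer(input_size)
  depth <- as.integer(depth)
  if (input_size %% 2L^depth != 0L) {
    stop("`input_size` must be divisible by 2^depth", call. = FALSE)
  }
  if (any(diff(pbp_bins) <= 0)) {
    stop("`pbp_bins` must be strictly increasing", call. = FALSE)
  }
  if (base_channels < 2L || base_channels %% 2L != 0L) {
    stop("`base_channels` must be an even integer >= 2", call. = FALSE)
  }
  structure(list(
    input_size = input_size,
    input_channels = as.integer(input_channels),
    base_channels = as.integer(base_channels),
    depth = depth,
    blur_kernel_size = as.integer(blur_kernel_size),
    mlp_ratio = as.integer(mlp_ratio),
    pbp_bins = as.integer(pbp_bins),
    aux_strides = as.integer(aux_strides)
  ), class = "cba_config")
}

init_conv <- function(cout, cin, k) {
  list(w = array(rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
                 c(cout, cin, k, k)),
       b = numeric(cout))
}

init_convt <- function(cin, cout, k = 3L) {
  list(w = array(rnorm(cin * cout * k * k, sd = sqrt(2 / (cin * k * k))),
                 c(cin, cout, k, k)),
       b = numeric(cout))
}

#' Parameters for one downsampling (DN) block
#'
#' A DN block doubles the channel count with a 3x3 convolution, applies the
#' blur attention module, and halves the spatial dims with anti-aliased max
#' pooling.
#'
#' @param in_channels Channels entering the block.
#' @param mlp_ratio Attention perceptron reduction ratio.
#' @return Parameter list with components `conv` and `att`.
#' @export
dn_params <- function(in_channels, mlp_ratio = 8L) {
  list(conv = init_conv(2L * in_channels, in_channels, 3L),
       att = attention_params(2L * in_channels, mlp_ratio))
}

#' Parameters for a pyramid blur pooling (PBP) module
#'
#' One dilated 3x3 convolution per pyramid bin, each mapping `channels` to
#' `channels / 4`.
#'
#' @param channels Channels of the map the module is applied to; must be
#'   divisible by 4.
#' @param bins Pyramid grid sizes.
#' @return List of per-branch convolution parameters.
#' @export
pbp_params <- function(channels, bins = c(1L, 2L, 4L, 8L)) {
  if (channels %% 4L != 0L) stop("`channels` must be divisible by 4", call. = FALSE)
  lapply(bins, function(b) init_conv(channels %/% 4L, channels, 3L))
}

#' Parameters for one upsampling (UP) block
#'
#' A PBP module over the fused decoder map (which doubles its channels)
#' followed by a 3x3 stride-2 transpose convolution that doubles the spatial
#' dims.
#'
#' @param in_channels Channels of the fused map entering the block.
#' @param out_channels Channels after the transpose convolution.
#' @param bins Pyramid grid sizes.
#' @return Parameter list with components `pbp` and `convt`.
#' @export
up_params <- function(in_channels, out_channels, bins = c(1L, 2L, 4L, 8L)) {
  list(pbp = pbp_params(in_channels, bins),
       convt = init_convt(2L * in_channels, out_channels))
}

# ---- tape-level blocks -----------------------------------------------------

ag_dn_block <- function(x, P, kernel) {
  h <- ag_relu(ag_conv2d(x, P$conv$w, P$conv$b))
  h <- ag_blur_attention(h, P$att, kernel)
  ag_blurdown(ag_maxdense(h), kernel, 2L)
}

ag_pbp <- function(x, P, bins, kernel) {
  d <- dim(x$value)
  blurred <- ag_blurdown(ag_maxdense(x), kernel, 1L)
  branches <- list(x)
  for (i in seq_along(bins)) {
    b <- bins[i]
    p <- ag_adaptavg(blurred, min(b, d[3]), min(b, d[4]))
    cv <- ag_relu(ag_conv2d(p, P[[i]]$w, P[[i]]$b, dilation = b))
    branches[[i + 1L]] <- ag_resize_nn(cv, d[3], d[4])
  }
  ag_concat(branches)
}

ag_up_block <- function(x, skips, P, bins, kernel) {
  if (length(skips) > 0L) x <- ag_concat(c(list(x), skips))
  h <- ag_pbp(x, P$pbp, bins, kernel)
  ag_relu(ag_convt2d(h, P$convt$w, P$convt$b))
}

# ---- functional block API (plain arrays in / out) --------------------------

#' Downsampling block
#'
#' 3x3 convolution doubling the channels, ReLU, blur attention, then
#' anti-aliased max pooling with stride 2. Spatial dims are halved.
#'
#' @param x Feature map with even spatial dims.
#' @param params Parameters from [dn_params()].
#' @param kernel Blur kernel.
#' @return Feature map with doubled channels and halved spatial dims.
#' @export
dn_block <- function(x, params, kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  if (any(dim(x)[3:4] %% 2L != 0L)) {
    stop("DN block requires even spatial dims", call. = FALSE)
  }
  ag_dn_block(ag_param(x), params_to_nodes(params), kernel)$value
}

#' Pyramid blur pooling module
#'
#' Pools the input to each pyramid grid (dense 2x2 max evaluation, low-pass
#' filtering, adaptive averaging to `bin x bin`), filters each pooled grid
#' with a dilated 3x3 convolution (dilation = bin) reducing channels to C/4,
#' upsamples every branch back to the input size with nearest-neighbour
#' interpolation, and concatenates the four branches with the input
#' (C + 4 * C/4 = 2C output channels).
#'
#' @param x Feature map whose channel count is divisible by 4.
#' @param params Parameters from [pbp_params()].
#' @param bins Pyramid grid sizes.
#' @param kernel Blur kernel.
#' @return Feature map with doubled channel count, same spatial dims.
#' @export
pbp_module <- function(x, params, bins = c(1L, 2L, 4L, 8L),
                       kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  ag_pbp(ag_param(x), params_to_nodes(params), bins, kernel)$value
}

#' Upsampling block
#'
#' Concatenates the decoder stream with its skip feature maps (if any),
#' applies pyramid blur pooling, and doubles the spatial dims with a 3x3
#' stride-2 transpose convolution.
#'
#' @param x Decoder feature map.
#' @param skip Optional list of skip feature maps with the same spatial dims
#'   as `x` (a single feature map is also accepted).
#' @param params Parameters from [up_params()].
#' @param bins Pyramid grid sizes.
#' @param kernel Blur kernel.
#' @return Feature map with doubled spatial dims.
#' @export
up_block <- function(x, skip = NULL, params, bins = c(1L, 2L, 4L, 8L),
                     kernel = make_blur_kernel(3L)) {
  x <- as_feature_map(x)
  skips <- list()
  if (!is.null(skip)) {
    if (!is.list(skip)) skip <- list(skip)
    skips <- lapply(skip, function(s) {
      s <- as_feature_map(s)
      if (!all(dim(s)[c(1, 3, 4)] == dim(x)[c(1, 3, 4)])) {
        stop("skip dims do not match the decoder stream", call. = FALSE)
      }
      ag_param(s)
    })
  }
  ag_up_block(ag_param(x), skips, params_to_nodes(params), bins, kernel)$value
}

#' Auxiliary strided features
#'
#' Extracts information from the stem-convoluted input through anti-aliased
#' convolutions with strides 2, 4 and 8, producing maps whose spatial sides
#' match the first three encoder levels (96/48/24 for a 192 input). These are
#' concatenated with the DN features of the same size in the decoder.
#'
#' @param c1_out Output of the stride-1 stem blur convolution.
#' @param params List of per-stride convolution parameters (fields `w`, `b`).
#' @param strides Integer strides, one per parameter set.
#' @param kernel Blur kernel.
#' @return List of feature maps, one per stride.
#' @export
aux_features <- function(c1_out, params, strides = c(2L, 4L, 8L),
                         kernel = make_blur_kernel(3L)) {
  c1_out <- as_feature_map(c1_out)
  Map(function(P, s) {
    blur_conv(c1_out, P$w, P$b, stride = s, kernel = kernel)
  }, params, as.integer(strides))
}

# ---- full network ----------------------------------------------------------

# channel widths of the fused decoder maps and transpose-conv outputs
decoder_widths <- function(config) {
  C0 <- config$base_channels
  enc <- C0 * 2L^seq_len(config$depth)
  D <- integer(config$depth)
  Tt <- integer(config$depth)
  for (j in seq_len(config$depth)) {
    lev <- config$depth - j + 1L
    D[j] <- if (j == 1L) enc[config$depth] else Tt[j - 1L] + enc[lev] + C0
    Tt[j] <- enc[lev] %/% 2L
  }
  list(enc = enc, fused = D, up_out = Tt)
}

#' Build the blur-attention segmentation network
#'
#' Assembles the stem blur convolution, `depth` DN blocks, auxiliary strided
#' skip convolutions, `depth` UP blocks with pyramid blur pooling, and a 1x1
#' convolution + sigmoid head into a segmentation model. Weights are drawn
#' from the current RNG state (or from `seed` if given), so a fixed seed gives
#' a bit-reproducible model.
#'
#' @param config A [cba_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `cba_network` with elements `config` and
#'   `params`.
#' @export
cba_network <- function(config = cba_config(), seed = NULL) {
  stopifnot(inherits(config, "cba_config"))
  if (!is.null(seed)) set.seed(seed)
  C0 <- config$base_channels
  wd <- decoder_widths(config)
  for (D in wd$fused) {
    if (D %% 4L != 0L) {
      stop("fused decoder channels (", D, ") not divisible by 4; ",
           "choose a different `base_channels`", call. = FALSE)
    }
  }
  params <- list(
    c1 = init_conv(C0, config$input_channels, 3L),
    aux = lapply(config$aux_strides, function(s) init_conv(C0, C0, 3L)),
    dn = lapply(seq_len(config$depth), function(i) {
      dn_params(C0 * 2L^(i - 1L), config$mlp_ratio)
    }),
    up = lapply(seq_len(config$depth), function(j) {
      up_params(wd$fused[j], wd$up_out[j], config$pbp_bins)
    }),
    head = init_conv(1L, wd$up_out[config$depth], 1L)
  )
  structure(list(config = config, params = params), class = "cba_network")
}

# forward pass on the tape; x is a node holding (N, Cin, S, S)
ag_cba_forward <- function(Pn, x, config) {
  k <- make_blur_kernel(config$blur_kernel_size)
  c1 <- ag_relu(ag_blurdown(ag_conv2d(x, Pn$c1$w, Pn$c1$b), k, 1L))
  aux <- Map(function(P, s) {
    ag_relu(ag_blurdown(ag_conv2d(c1, P$w, P$b), k, s))
  }, Pn$aux, as.list(config$aux_strides))
  cur <- c1
  dn_out <- vector("list", config$depth)
  for (i in seq_len(config$depth)) {
    cur <- ag_dn_block(cur, Pn$dn[[i]], k)
    dn_out[[i]] <- cur
  }
  for (j in seq_len(config$depth)) {
    lev <- config$depth - j + 1L
    skips <- if (j == 1L) list() else list(dn_out[[lev]], aux[[lev]])
    cur <- ag_up_block(cur, skips, Pn$up[[j]], config$pbp_bins, k)
  }
  ag_sigmoid(ag_conv2d(cur, Pn$head$w, Pn$head$b))
}

#' Forward pass
#'
#' Runs the network on a batch of images and returns per-pixel foreground
#' probabilities. Inference is deterministic: the same input and parameters
#' give bit-identical output.
#'
#' @param model A [cba_network()].
#' @param x Feature map `(batch, channels, S, S)` with `S` divisible by
#'   `2^depth`, or a plain `S x S` matrix.
#' @return Array `(batch, 1, S, S)` of probabilities in (0, 1).
#' @export
cba_forward <- function(model, x) {
  stopifnot(inherits(model, "cba_network"))
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[2] != model$config$input_channels) {
    stop("input channel count does not match the model", call. = FALSE)
  }
  if (any(d[3:4] %% 2L^model$config$depth != 0L)) {
    stop("spatial dims must be divisible by 2^depth", call. = FALSE)
  }
  Pn <- params_to_nodes(model$params)
  ag_cba_forward(Pn, ag_param(x), model$config)$value
}

#' Count trainable parameters
#'
#' @param model A [cba_network()], or any nested list of numeric arrays.
#' @return Total number of trainable scalar parameters.
#' @export
count_parameters <- function(model) {
  params <- if (inherits(model, "cba_network")) model$params else model
  sum(unlist(rapply(params, length, classes = c("numeric", "matrix", "array"),
                    how = "unlist")))
}

#' @export
print.cba_network <- function(x, ...) {
  cfg <- x$config
  cat("<cba_network> input", cfg$input_size, "x", cfg$input_size,
      "base", cfg$base_channels, "depth", cfg$depth,
      "| parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}
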