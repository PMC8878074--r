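#' Training configuration
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Images per gradient step.
#' @param lr Adam learning rate.
#' @param optimizer Only `"adam"` is provided.
#' @param patience Early-stopping patience in epochs (on validation loss).
#' @param seed Integer seed controlling the split, shuffling and any
#'   generated data.
#' @param val_fraction Fraction of the data held out for validation,
#'   in (0, 1).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, lr = 1e-3,
                         optimizer = "adam", patience = 10L, seed = 42L,
                         val_fraction = 0.2) {
  stopifnot(epochs >= 0, batch_size >= 1,
            val_fraction > 0, val_fraction < 1)
  optimizer <- match.arg(optimizer, "adam")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, optimizer = optimizer, patience = as.integer(patience),
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "train_config")
}

# composite loss on probabilities: binary cross-entropy + (1 - soft Dice),
# equal weights; returns the loss value and its gradient w.r.t. p
bce_dice_loss <- function(p, y) {
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  bce <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  den <- sp + sy + 1
  soft_dice <- (2 * spy + 1) / den
  grad <- (-(y / pc) + (1 - y) / (1 - pc)) / length(p) -
    (2 * y * den - (2 * spy + 1)) / den^2
  list(loss = bce + (1 - soft_dice), grad = grad)
}

map2_params <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) map2_params(f, x, y), a, b) else f(a, b)
}
map3_params <- function(f, a, b, c) {
  if (is.list(a)) Map(function(x, y, z) map3_params(f, x, y, z), a, b, c) else f(a, b, c)
}
zeros_like <- function(p) rapply(p, function(x) { x[] <- 0; x },
                                 classes = c("numeric", "matrix", "array"),
                                 how = "replace")

adam_new <- function(params) list(m = zeros_like(params), v = zeros_like(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map2_params(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- map3_params(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# stack a list of (image, labels) pairs into a batch and its binary target
make_batch <- function(data, idx) {
  S1 <- nrow(data[[idx[1]]]$image); S2 <- ncol(data[[idx[1]]]$image)
  x <- array(0, c(length(idx), 1L, S1, S2))
  y <- array(0, c(length(idx), 1L, S1, S2))
  for (i in seq_along(idx)) {
    x[i, 1L, , ] <- data[[idx[i]]]$image
    y[i, 1L, , ] <- as.numeric(data[[idx[i]]]$labels > 0)
  }
  list(x = x, y = y)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

eval_loss <- function(params, config_net, data, idx, batch_size) {
  total <- 0; npix <- 0
  for (b in batch_indices(length(idx), batch_size)) {
    bt <- make_batch(data, idx[b])
    Pn <- params_to_nodes(params)
    out <- ag_cba_forward(Pn, ag_param(bt$x), config_net)
    l <- bce_dice_loss(out$value, bt$y)
    total <- total + l$loss * length(b)
    npix <- npix + length(b)
  }
  total / npix
}

#' Train a segmentation network
#'
#' Minimizes binary cross-entropy plus soft-Dice loss with Adam on a dataset
#' of `(image, labels)` pairs already at the network input size. The data are
#' split into training and validation subsets, shuffled per epoch, and the
#' parameters with the best validation loss are returned. Training is seeded
#' end-to-end: the same model, data and seed give identical loss histories.
#'
#' @param model A [cba_network()].
#' @param data List of `list(image, labels)` pairs; `image` is an
#'   `S x S` matrix in `[0, 1]`, `labels` an instance label map (any pixel
#'   > 0 is foreground for the loss).
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best-validation parameters) and `history`
#'   (data frame `epoch`, `train_loss`, `val_loss`).
#' @export
train <- function(model, data, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "cba_network"), length(data) >= 2L)
  if (config$epochs == 0L) {
    return(list(model = model,
                history = data.frame(epoch = integer(), train_loss = numeric(),
                                     val_loss = numeric())))
  }
  set.seed(config$seed)
  n <- length(data)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- model$params
  state <- adam_new(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf
  best_params <- params
  wait <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    for (b in batch_indices(length(ord), config$batch_size)) {
      bt <- make_batch(data, ord[b])
      Pn <- params_to_nodes(params)
      out <- ag_cba_forward(Pn, ag_param(bt$x), model$config)
      l <- bce_dice_loss(out$value, bt$y)
      if (!is.finite(l$loss)) {
        stop("training diverged: non-finite loss at epoch ", ep, call. = FALSE)
      }
      ag_backward(out, l$grad)
      grads <- nodes_to_grads(Pn)
      st <- adam_step(params, grads, state, config$lr)
      params <- st$params
      state <- st$state
      ep_loss <- ep_loss + l$loss * length(b)
    }
    ep_loss <- ep_loss / length(ord)
    vl <- eval_loss(params, model$config, data, val_idx, config$batch_size)
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                         val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %d  train %.4f  val %.4f", ep, ep_loss, vl))
    }
    if (vl < best_val) {
      best_val <- vl
      best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  model$params <- best_params
  list(model = model, history = history)
}

# resize an instance label map with nearest-neighbour sampling
resize_mask_nn <- function(mask, size) {
  if (nrow(mask) == size && ncol(mask) == size) return(mask)
  iy <- pmin(floor((seq_len(size) - 0.5) * nrow(mask) / size) + 1L, nrow(mask))
  ix <- pmin(floor((seq_len(size) - 0.5) * ncol(mask) / size) + 1L, ncol(mask))
  mask[iy, ix, drop = FALSE]
}

# convert corpus entries (image + instance labels of any size) to network
# input pairs
corpus_to_pairs <- function(corpus, size) {
  lapply(corpus, function(e) {
    list(image = normalize_image(e$image, size),
         labels = relabel_contiguous(resize_mask_nn(e$labels, size)))
  })
}

# default synthetic pretraining preset at a given input size: nucleus radius
# scales with the side so density and appearance stay comparable
synthetic_preset <- function(size, seed, mode = "fluorescence") {
  scene_config(size = size, n_nuclei = c(3L, 7L),
               radius = c(max(3, size / 16), max(5, size / 8)),
               touching_prob = 0.2, illum_amplitude = 0.3,
               gauss_sd = 0.03, poisson_peak = 200, mode = mode, seed = seed)
}

#' Pretrain on a surrogate corpus, then fine-tune
#'
#' Trains the network first on a pretraining corpus (by default, generated
#' synthetic fluorescence scenes) and then continues training on the
#' fine-tuning corpus from the pretrained weights. Both phases are logged
#' separately. Pretraining on a surrogate corpus curbs overfitting when the
#' task corpus is small.
#'
#' @param finetune_data List of `(image, labels)` pairs at the network input
#'   size (the task corpus).
#' @param config A [train_config()] for the fine-tuning phase.
#' @param model A [cba_network()]; if `NULL`, one is built from `net_config`
#'   with seed `config$seed`.
#' @param net_config Architecture used when `model` is `NULL`.
#' @param pretrain_data `"synthetic"` (generate `n_pretrain` scenes), or a
#'   list of `(image, labels)` pairs, or `NULL` to skip pretraining.
#' @param pretrain_epochs Epochs of the pretraining phase (0 skips it).
#' @param n_pretrain Number of synthetic pretraining scenes.
#' @return List with `model`, `pretrain_history` (NULL if skipped) and
#'   `finetune_history`.
#' @export
pretrain_finetune <- function(finetune_data, config = train_config(),
                              model = NULL, net_config = cba_config(),
                              pretrain_data = "synthetic",
                              pretrain_epochs = config$epochs,
                              n_pretrain = 64L) {
  if (is.null(model)) model <- cba_network(net_config, seed = config$seed)
  size <- model$config$input_size
  pre_hist <- NULL
  pretrained <- FALSE
  if (!is.null(pretrain_data) && pretrain_epochs > 0L) {
    pretrained <- TRUE
    if (identical(pretrain_data, "synthetic")) {
      scenes <- generate_scenes(synthetic_preset(size, seed = config$seed), n_pretrain)
      pretrain_data <- lapply(scenes, function(s) {
        list(image = s$image, labels = s$labels)
      })
    }
    pre_cfg <- config
    pre_cfg$epochs <- as.integer(pretrain_epochs)
    pre <- train(model, pretrain_data, pre_cfg)
    model <- pre$model
    pre_hist <- pre$history
  }
  if (config$epochs > 0L) {
    ft_cfg <- config
    # distinct shuffling stream after a pretraining phase; without one, the
    # call is behaviourally identical to train()
    if (pretrained) ft_cfg$seed <- config$seed + 1L
    ft <- train(model, finetune_data, ft_cfg)
    model <- ft$model
    ft_hist <- ft$history
  } else {
    ft_hist <- NULL
  }
  list(model = model, pretrain_history = pre_hist, finetune_history = ft_hist)
}
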