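#' Desk-scale synthetic segmentation benchmark
#'
#' Reproducible end-to-end experiment: generates synthetic fluorescence
#' scenes, trains a reduced network on part of them, and evaluates pixel
#' Dice and the aggregated Jaccard index on a held-out remainder. All
#' randomness (scene content, weight initialization, shuffling) derives from
#' `seed`.
#'
#' @param seed Master seed of the experiment.
#' @param n_scenes Total number of scenes; `holdout_fraction` of them are
#'   held out for evaluation.
#' @param input_size Network input side (scenes are generated at this size).
#' @param base_channels Width of the reduced network.
#' @param epochs Training epochs.
#' @param holdout_fraction Fraction of scenes held out.
#' @return List with `dsc` and `aji` (held-out means), `per_image` (data
#'   frame of per-scene metrics), `history` (training losses) and `model`.
#' @export
synthetic_benchmark <- function(seed = 42L, n_scenes = 200L, input_size = 64L,
                                base_channels = 8L, epochs = 10L,
                                holdout_fraction = 0.2) {
  scenes <- generate_scenes(synthetic_preset(input_size, seed = seed), n_scenes)
  n_hold <- max(1L, round(holdout_fraction * n_scenes))
  hold <- scenes[seq_len(n_hold) + (n_scenes - n_hold)]
  data <- lapply(scenes[seq_len(n_scenes - n_hold)], function(s) {
    list(image = s$image, labels = s$labels)
  })
  model <- cba_network(cba_config(input_size = input_size,
                                  base_channels = base_channels), seed = seed)
  fit <- train(model, data, train_config(epochs = epochs, batch_size = 8L,
                                         seed = seed))
  rows <- t(vapply(hold, function(h) {
    pr <- predict_nuclei(fit$model, h$image)
    c(dsc = dice(pr$labels > 0, h$labels > 0), aji = aji(h$labels, pr$labels))
  }, c(dsc = 0, aji = 0)))
  list(dsc = mean(rows[, "dsc"]), aji = mean(rows[, "aji"]),
       per_image = as.data.frame(rows), history = fit$history,
       model = fit$model)
}

# harder second synthetic style used as the fine-tuning task: smaller,
# noisier, more clustered nuclei under a stronger illumination gradient
finetune_style <- function(size, seed) {
  scene_config(size = size, n_nuclei = c(4L, 9L), radius = c(3, 5.5),
               eccentricity = c(1, 1.8), touching_prob = 0.4,
               illum_amplitude = 0.5, gauss_sd = 0.06, poisson_peak = 120,
               mode = "fluorescence", seed = seed)
}

#' Pretraining-benefit comparison
#'
#' For each seed, trains the same reduced architecture twice on a small
#' corpus of "hard-style" synthetic scenes at an equal total epoch budget:
#' once fine-tuning from weights pretrained on a larger corpus of
#' standard-style scenes (half the epochs in each phase), and once from
#' scratch. Both models are scored by mean Dice on held-out scenes of the
#' hard style, mirroring a with/without-pretraining ablation.
#'
#' @param seeds Integer vector of experiment seeds.
#' @param input_size,base_channels Reduced architecture.
#' @param total_epochs Total epoch budget per arm (split evenly across the
#'   two phases in the pretraining arm).
#' @param n_finetune Size of the small fine-tuning corpus.
#' @param n_pretrain Size of the synthetic pretraining corpus.
#' @param n_holdout Held-out scenes of the fine-tuning style.
#' @return Data frame with one row per seed: `seed`, `pretrain_dsc`,
#'   `scratch_dsc`.
#' @export
pretrain_comparison <- function(seeds = 101:105, input_size = 64L,
                                base_channels = 8L, total_epochs = 10L,
                                n_finetune = 10L, n_pretrain = 64L,
                                n_holdout = 16L) {
  cfgnet <- cba_config(input_size = input_size, base_channels = base_channels)
  half <- total_epochs %/% 2L
  rows <- lapply(seeds, function(seed) {
    ft_scenes <- generate_scenes(finetune_style(input_size, seed), n_finetune)
    ft_data <- lapply(ft_scenes, function(s) list(image = s$image, labels = s$labels))
    hold <- generate_scenes(finetune_style(input_size, seed + 5000L), n_holdout)
    score <- function(model) {
      mean(vapply(hold, function(h) {
        pr <- predict_nuclei(model, h$image)
        dice(pr$labels > 0, h$labels > 0)
      }, 0))
    }
    tc <- train_config(epochs = half, batch_size = 8L, seed = seed)
    with_pre <- pretrain_finetune(ft_data, tc, net_config = cfgnet,
                                  pretrain_data = "synthetic",
                                  pretrain_epochs = half,
                                  n_pretrain = n_pretrain)
    scratch <- train(cba_network(cfgnet, seed = seed), ft_data,
                     train_config(epochs = total_epochs, batch_size = 8L,
                                  seed = seed))
    data.frame(seed = seed, pretrain_dsc = score(with_pre$model),
               scratch_dsc = score(scratch$model))
  })
  do.call(rbind, rows)
}
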