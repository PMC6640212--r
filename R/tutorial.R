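#' Six-channel DoG filter bank for the digit-style front end
#'
#' Three centre--surround scales, each in an ON-centre and an OFF-centre
#' variant (window sizes 3, 7 and 13 with Gaussian width pairs 1/3 vs 2/3,
#' 7/9 vs 14/9, and 13/9 vs 26/9 pixels), packed into one bank with
#' padding 6 so the spatial size of the input is preserved. Six DoG
#' channels are the standard retina-like front end for this family of
#' networks.
#'
#' @param clip_threshold responses below this value produce no spikes;
#'   the default suits images with intensities in [0, 1].
#' @return a [filter_bank()] of six kernels.
#' @export
default_dog_bank <- function(clip_threshold = 0.1) {
  specs <- list(c(3, 3 / 9, 6 / 9), c(3, 6 / 9, 3 / 9),
                c(7, 7 / 9, 14 / 9), c(7, 14 / 9, 7 / 9),
                c(13, 13 / 9, 26 / 9), c(13, 26 / 9, 13 / 9))
  kernels <- lapply(specs, function(s)
    make_dog_kernel(s[1L], s[2L], s[3L]))
  filter_bank(kernels, padding = 6L, clip_threshold = clip_threshold)
}

#' Image-to-spike-wave encoder
#'
#' Returns the transform used as a dataset's \code{transform}: the image
#' is filtered by the bank, locally normalized, and converted to an
#' accumulative spike-wave by rank-order latency coding.
#'
#' @param bank a [filter_bank()]; defaults to [default_dog_bank()].
#' @param norm_region odd side of the local-normalization neighbourhood.
#' @param t_max number of discrete time-steps of the code.
#' @return a function mapping an image matrix to a spike-wave tensor.
#' @export
input_encoder <- function(bank = default_dog_bank(), norm_region = 9L,
                          t_max = 15L) {
  force(bank); force(norm_region); force(t_max)
  function(image) {
    map <- apply_filter_bank(image, bank)
    map <- local_normalization(map, norm_region)
    intensity_to_latency(map, t_max)
  }
}

#' Three-stage digit-recognition network preset
#'
#' Builds the S1 -> C1 -> S2 -> C2 -> S3 -> (global) C3 architecture at
#' desk scale: two STDP-trained feature stages with local max-pooling and
#' an R-STDP decision stage whose weights are kept in [0.2, 0.8] with the
#' stabilizer off. Each class owns an equal block of decision features.
#' Weight tensors are initialized from per-layer normal draws seeded by a
#' single run-level seed, so construction is reproducible.
#'
#' @param n_classes number of classes.
#' @param in_features input channels (6 for [default_dog_bank()]).
#' @param s1_features,s2_features feature counts of the first two stages.
#' @param features_per_class decision features allotted to each class.
#' @param thresholds firing thresholds of the first two stages.
#' @param seed run-level seed for weight initialization.
#' @return a [network_spec()].
#' @export
tutorial_network <- function(n_classes = 2L, in_features = 6L,
                             s1_features = 8L, s2_features = 12L,
                             features_per_class = 10L,
                             thresholds = c(15, 10), seed = 1L) {
  with_preserved_rng({
    set.seed(as.integer(seed))
    s3_features <- n_classes * features_per_class
    s1 <- conv_stage(
      conv_layer(in_features, s1_features, 5L),
      threshold = thresholds[1L], k = 5L, radius = 3L,
      pool = pool_spec(2L),
      rule = stdp_rule(0.004, -0.003))
    s2 <- conv_stage(
      conv_layer(s1_features, s2_features, 3L),
      threshold = thresholds[2L], k = 8L, radius = 1L,
      pool = pool_spec(2L),
      rule = stdp_rule(0.004, -0.003))
    s3 <- conv_stage(
      conv_layer(s2_features, s3_features, 5L,
                 init_mean = 0.5, init_sd = 0.05),
      threshold = NA, k = 1L, radius = 0L,
      rule = rstdp_pair(
        stdp_rule(0.004, -0.003, 0.2, 0.8, use_stabilizer = FALSE),
        stdp_rule(-0.004, 0.0005, 0.2, 0.8, use_stabilizer = FALSE)))
    network_spec(list(s1, s2, s3),
                 decision_map = rep(seq_len(n_classes) - 1L,
                                    each = features_per_class))
  })
}

#' Run the full desk-scale experiment
#'
#' Generates the synthetic oriented-bar dataset, encodes and caches it,
#' trains S1 and S2 layer-wise with STDP (2 and 4 epochs), then trains the
#' decision stage with R-STDP, stopping early once training accuracy
#' reaches \code{target_accuracy}. Everything is driven by one root seed.
#'
#' @param n_classes number of classes.
#' @param samples_per_class images per class.
#' @param image_size image side length.
#' @param noise_level additive noise standard deviation.
#' @param rl_epochs maximum number of R-STDP epochs.
#' @param target_accuracy early-stopping training accuracy in [0, 1].
#' @param seed root seed for the dataset and weight initialization.
#' @param verbose print per-epoch counters.
#' @return list with the trained \code{net}, final training
#'   \code{counters}, per-epoch \code{history}, the number of
#'   \code{epochs_run}, and the encoded \code{dataset}.
#' @export
run_experiment <- function(n_classes = 2L, samples_per_class = 30L,
                           image_size = 24L, noise_level = 0.05,
                           rl_epochs = 20L, target_accuracy = 0.9,
                           seed = 1L, verbose = FALSE) {
  images <- generate_synthetic_dataset(n_classes, samples_per_class,
                                       image_size, noise_level, seed)
  enc <- input_encoder()
  ds <- cached_dataset(sw_dataset(images$items, images$labels,
                                  transform = enc))
  net <- tutorial_network(n_classes = n_classes, seed = seed + 1L)
  net <- train_unsupervised(net, ds, 1L, epochs = 2L)
  net <- train_unsupervised(net, ds, 2L, epochs = 4L)
  history <- list()
  counters <- NULL
  epochs_run <- 0L
  for (e in seq_len(rl_epochs)) {
    res <- train_rl(net, ds, epochs = 1L)
    net <- res$net
    counters <- res$counters
    history[[e]] <- counters
    epochs_run <- e
    acc <- counters$correct /
      (counters$correct + counters$wrong + counters$silent)
    if (verbose)
      cat(sprintf("epoch %2d: correct %d wrong %d silent %d (%.3f)\n",
                  e, counters$correct, counters$wrong, counters$silent,
                  acc))
    if (acc >= target_accuracy) break
  }
  list(net = net, counters = counters, history = history,
       epochs_run = epochs_run, dataset = ds)
}
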