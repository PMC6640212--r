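#' One convolution--fire--pool stage of a spiking network
#'
#' Bundles a [conv_layer()] with its firing threshold, winner-take-all
#' parameters, input padding, optional pooling, and learning rule. A stage
#' with \code{threshold = NA} uses infinite-threshold firing
#' ([fire_infinite()]): its neurons spike only at the final time-step,
#' which is how the decision layer exposes membrane potentials for
#' classification.
#'
#' @param conv a [conv_layer()].
#' @param threshold firing threshold, or \code{NA} for the
#'   infinite-threshold decision stage.
#' @param k number of winners selected during training.
#' @param radius Chebyshev lateral-inhibition radius used during training.
#' @param padding spatial zero-padding applied to the stage input; the
#'   default \code{floor(kernel/2)} avoids information loss at borders.
#' @param pool optional [pool_spec()] applied to the stage's output spikes.
#' @param rule an [stdp_rule()] for unsupervised stages or an
#'   [rstdp_pair()] for the reinforcement stage; \code{NULL} for frozen
#'   stages.
#' @return an object of class \code{"conv_stage"}.
#' @export
conv_stage <- function(conv, threshold = NA, k = 1L, radius = 0L,
                       padding = conv$kernel_size %/% 2L, pool = NULL,
                       rule = NULL) {
  stopifnot(inherits(conv, "conv_layer"))
  if (!is.null(pool)) stopifnot(inherits(pool, "pool_spec"))
  if (!is.null(rule) &&
      !inherits(rule, "stdp_rule") && !inherits(rule, "rstdp_pair"))
    stop("`rule` must be an stdp_rule or an rstdp_pair")
  structure(list(conv = conv, threshold = threshold, k = as.integer(k),
                 radius = as.integer(radius),
                 padding = as.integer(rep(padding, length.out = 2L)),
                 pool = pool, rule = rule),
            class = "conv_stage")
}

#' Feedforward spiking network specification
#'
#' An ordered list of [conv_stage()]s realizing the alternating
#' convolution (S) / pooling (C) topology, plus a decision map assigning a
#' class label to every feature of the final stage. The final pooling is
#' global: the decision is the label of the single most salient neuron of
#' the last stage, or silence when nothing fires.
#'
#' @param stages list of [conv_stage()] objects.
#' @param decision_map vector of class labels, one per output feature of
#'   the last stage.
#' @return an object of class \code{"network_spec"}.
#' @export
network_spec <- function(stages, decision_map) {
  if (!is.list(stages) || length(stages) == 0L ||
      !all(vapply(stages, inherits, logical(1), "conv_stage")))
    stop("`stages` must be a non-empty list of conv_stage objects")
  n_last <- stages[[length(stages)]]$conv$out_features
  if (length(decision_map) != n_last)
    stop("`decision_map` must have one label per final feature (",
         n_last, ")")
  for (i in seq_along(stages)[-1L]) {
    if (stages[[i]]$conv$in_features != stages[[i - 1L]]$conv$out_features)
      stop("stage ", i, " expects ", stages[[i]]$conv$in_features,
           " input features but stage ", i - 1L, " outputs ",
           stages[[i - 1L]]$conv$out_features)
  }
  structure(list(stages = stages, decision_map = decision_map),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("network_spec with", length(x$stages), "conv stages:\n")
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  S%d: %d -> %d, kernel %s, threshold %s%s\n", i,
                s$conv$in_features, s$conv$out_features,
                paste(s$conv$kernel_size, collapse = "x"),
                if (is.na(s$threshold)) "Inf" else s$threshold,
                if (is.null(s$pool)) "" else
                  paste0(", pool ", paste(s$pool$window, collapse = "x"))))
  }
  cat("  decision map over", length(x$decision_map), "features\n")
  invisible(x)
}

# pad -> convolve -> fire for one stage; infinite threshold on the last
run_stage <- function(wave, stage, last) {
  x <- pad_wave(wave, stage$padding)
  pot <- conv_forward(x, stage$conv)
  ft <- if (last) fire_infinite(pot, return_thresholded = TRUE)
        else fire(pot, stage$threshold, return_thresholded = TRUE)
  list(input = x, potentials = ft$potentials, spikes = ft$spikes)
}

decision_from_winners <- function(net, winners) {
  if (is.null(winners) || nrow(winners) == 0L) return(NA)
  net$decision_map[[winners$feature[1L]]]
}

#' Test-mode forward pass and decision
#'
#' Runs the stimulus through every stage (padded convolution, firing,
#' pooling), using infinite-threshold firing for the last stage, then
#' picks the single global winner from the final thresholded potentials
#' (the global max-pooling equivalent) and maps its feature through the
#' decision map. Returns \code{NA} (silence) when no final-stage neuron
#' has a non-zero potential.
#'
#' @param net a [network_spec()].
#' @param wave input spike-wave tensor.
#' @return a class label, or \code{NA} for a silent stimulus.
#' @export
forward_test <- function(net, wave) {
  stopifnot(inherits(net, "network_spec"))
  n <- length(net$stages)
  for (s in seq_len(n)) {
    stage <- net$stages[[s]]
    out <- run_stage(wave, stage, last = (s == n))
    if (s == n) {
      winners <- get_k_winners(out$potentials, k = 1L,
                               inhibition_radius = 0L)
      return(decision_from_winners(net, winners))
    }
    wave <- out$spikes
    if (!is.null(stage$pool)) wave <- pool(wave, stage$pool)
  }
}

#' Training-mode forward pass with saved plasticity context
#'
#' Identical stage sequence to [forward_test()] but interrupted after
#' \code{max_layer} stages; winners are selected there with the stage's
#' own k and inhibition radius, and everything plasticity needs (the
#' stage's padded input, thresholded potentials, output spikes, winners)
#' is returned as the forward context. When \code{max_layer} is the last
#' stage the decision is returned too.
#'
#' @param net a [network_spec()].
#' @param wave input spike-wave tensor.
#' @param max_layer stage index at which to stop (1-based).
#' @return list with elements \code{layer} (the index), \code{context}
#'   (see [reward()]) and \code{decision} (\code{NULL} unless the last
#'   stage was reached).
#' @export
forward_train <- function(net, wave, max_layer) {
  stopifnot(inherits(net, "network_spec"))
  n <- length(net$stages)
  if (max_layer < 1L || max_layer > n)
    stop("`max_layer` must be between 1 and ", n)
  for (s in seq_len(max_layer)) {
    stage <- net$stages[[s]]
    out <- run_stage(wave, stage, last = (s == n))
    if (s == max_layer) {
      winners <- get_k_winners(out$potentials, k = stage$k,
                               inhibition_radius = stage$radius)
      context <- list(input = out$input, potentials = out$potentials,
                      output = out$spikes, winners = winners)
      decision <- if (s == n) decision_from_winners(net, winners) else NULL
      return(list(layer = max_layer, context = context,
                  decision = decision))
    }
    wave <- out$spikes
    if (!is.null(stage$pool)) wave <- pool(wave, stage$pool)
  }
}

#' Layer-wise unsupervised STDP training
#'
#' Presents every sample of the dataset \code{epochs} times, running the
#' training forward pass up to \code{layer_idx} and applying that stage's
#' STDP rule to its winners. Earlier layers are assumed already trained
#' (the layer-wise protocol); no other layer's weights change. Whether the
#' earlier layers were actually trained is the caller's responsibility and
#' is not detectable here.
#'
#' @param net a [network_spec()].
#' @param dataset a dataset of spike-wave stimuli.
#' @param layer_idx index of the stage to train.
#' @param epochs number of passes over the dataset (0 returns the network
#'   unchanged).
#' @return the network with the trained stage updated.
#' @export
train_unsupervised <- function(net, dataset, layer_idx, epochs = 1L) {
  stopifnot(inherits(net, "network_spec"))
  stage <- net$stages[[layer_idx]]
  if (!inherits(stage$rule, "stdp_rule"))
    stop("stage ", layer_idx, " has no stdp_rule")
  n <- dataset_length(dataset)
  for (e in seq_len(epochs)) {
    for (i in seq_len(n)) {
      wave <- dataset_get(dataset, i)$sample
      fwd <- forward_train(net, wave, layer_idx)
      net$stages[[layer_idx]]$conv <- stdp_step(
        stage$rule, fwd$context$input, fwd$context$potentials,
        fwd$context$output, fwd$context$winners,
        net$stages[[layer_idx]]$conv)
      stage <- net$stages[[layer_idx]]
    }
  }
  net
}

eval_counters <- function(correct = 0L, wrong = 0L, silent = 0L) {
  structure(list(correct = as.integer(correct), wrong = as.integer(wrong),
                 silent = as.integer(silent)), class = "eval_counters")
}

#' @export
print.eval_counters <- function(x, ...) {
  n <- x$correct + x$wrong + x$silent
  cat(sprintf("correct %d / wrong %d / silent %d (n = %d, accuracy %.3f)\n",
              x$correct, x$wrong, x$silent, n,
              if (n > 0) x$correct / n else NA_real_))
  invisible(x)
}

#' Reinforcement training of the decision stage (R-STDP)
#'
#' For every labeled sample: run the full training forward pass, compare
#' the decision with the label, and apply the reward rule on a match or
#' the punishment (anti-STDP) rule on a mismatch. Silent samples trigger
#' no plasticity but are counted. Counters satisfy
#' \code{correct + wrong + silent = n} in every epoch.
#'
#' @param net a [network_spec()] whose last stage carries an
#'   [rstdp_pair()].
#' @param dataset labeled dataset of spike-wave stimuli.
#' @param epochs number of passes over the dataset.
#' @return list with elements \code{net} (updated), \code{counters} (the
#'   last epoch's [eval_counters]) and \code{history} (per-epoch list of
#'   counters).
#' @export
train_rl <- function(net, dataset, epochs = 1L) {
  stopifnot(inherits(net, "network_spec"))
  last <- length(net$stages)
  pair <- net$stages[[last]]$rule
  if (!inherits(pair, "rstdp_pair"))
    stop("the last stage must carry an rstdp_pair")
  n <- dataset_length(dataset)
  history <- vector("list", epochs)
  counters <- eval_counters()
  for (e in seq_len(epochs)) {
    counters <- eval_counters()
    for (i in seq_len(n)) {
      item <- dataset_get(dataset, i)
      if (is.null(item$label)) stop("train_rl needs labeled samples")
      if (!item$label %in% net$decision_map)
        stop("label ", item$label, " is outside the decision map")
      fwd <- forward_train(net, item$sample, last)
      d <- fwd$decision
      if (is.na(d)) {
        counters$silent <- counters$silent + 1L
      } else if (isTRUE(d == item$label)) {
        counters$correct <- counters$correct + 1L
        net$stages[[last]]$conv <- reward(pair, net$stages[[last]]$conv,
                                          fwd$context)
      } else {
        counters$wrong <- counters$wrong + 1L
        net$stages[[last]]$conv <- punish(pair, net$stages[[last]]$conv,
                                          fwd$context)
      }
    }
    history[[e]] <- counters
  }
  list(net = net, counters = counters, history = history)
}

#' Evaluate a network on a labeled dataset
#'
#' Pure test-mode evaluation: [forward_test()] per sample, no plasticity,
#' no state change; evaluating twice gives identical counters.
#'
#' @param net a [network_spec()].
#' @param dataset labeled dataset of spike-wave stimuli.
#' @return an [eval_counters] object.
#' @export
evaluate_network <- function(net, dataset) {
  stopifnot(inherits(net, "network_spec"))
  counters <- eval_counters()
  for (i in seq_len(dataset_length(dataset))) {
    item <- dataset_get(dataset, i)
    d <- forward_test(net, item$sample)
    if (is.na(d)) counters$silent <- counters$silent + 1L
    else if (isTRUE(d == item$label))
      counters$correct <- counters$correct + 1L
    else counters$wrong <- counters$wrong + 1L
  }
  counters
}
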