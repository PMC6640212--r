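#' STDP learning rule
#'
#' Parameters of the simplified spike-timing-dependent plasticity rule used
#' with time-to-first-spike coding: a synapse onto a winning post-synaptic
#' neuron is potentiated by rate \code{a_plus} when its pre-synaptic neuron
#' fired at or before the post-synaptic spike, and depressed by rate
#' \code{a_minus} otherwise (including pre-synaptic silence). With the
#' stabilizer on, the update is multiplied by \code{(W - LB) * (UB - W)},
#' which slows learning near the bounds and makes them fixed points; with
#' it off the bare rate is applied and the weight clamped into
#' \code{[LB, UB]}.
#'
#' @param a_plus learning rate for the potentiation branch.
#' @param a_minus learning rate for the depression branch (typically
#'   negative).
#' @param lower_bound,upper_bound weight bounds, \code{LB < UB}.
#' @param use_stabilizer logical; multiplicative soft-bounding on/off.
#' @return an object of class \code{"stdp_rule"}.
#' @export
stdp_rule <- function(a_plus, a_minus, lower_bound = 0, upper_bound = 1,
                      use_stabilizer = TRUE) {
  if (!is.finite(a_plus) || !is.finite(a_minus))
    stop("learning rates must be finite")
  if (lower_bound >= upper_bound)
    stop("`lower_bound` must be below `upper_bound`")
  structure(list(a_plus = a_plus, a_minus = a_minus,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 use_stabilizer = isTRUE(use_stabilizer)),
            class = "stdp_rule")
}

#' Reward-modulated STDP pair
#'
#' Reward-modulated STDP is realized as two plain STDP rules: the reward
#' rule is ordinary STDP, and the punishment (anti-STDP) rule has
#' learning-rate signs negated, so a wrong decision pushes the responsible
#' synapses in the opposite direction. Magnitudes may differ between the
#' two rules.
#'
#' @param stdp the reward-side [stdp_rule()].
#' @param anti_stdp the punishment-side rule; its \code{a_plus} /
#'   \code{a_minus} signs must oppose those of \code{stdp}.
#' @return an object of class \code{"rstdp_pair"}.
#' @export
rstdp_pair <- function(stdp, anti_stdp) {
  stopifnot(inherits(stdp, "stdp_rule"), inherits(anti_stdp, "stdp_rule"))
  if (sign(anti_stdp$a_plus) == sign(stdp$a_plus) && stdp$a_plus != 0)
    stop("`anti_stdp$a_plus` must have the opposite sign of `stdp$a_plus`")
  if (sign(anti_stdp$a_minus) == sign(stdp$a_minus) && stdp$a_minus != 0)
    stop("`anti_stdp$a_minus` must have the opposite sign of `stdp$a_minus`")
  structure(list(stdp = stdp, anti_stdp = anti_stdp), class = "rstdp_pair")
}

#' Apply one STDP update to the winners of a forward pass
#'
#' For every winner \code{i} (a post-synaptic neuron selected by
#' [get_k_winners()]) and every synapse \code{j} in its receptive field
#' (valid-convolution geometry: input rows \code{r .. r + K_h - 1}, cols
#' \code{c .. c + K_w - 1}, all input features), compares the pre-synaptic
#' first-spike step \code{T_j} (silence counts as later than everything)
#' with the winner's firing step \code{T_i}: \code{T_j <= T_i} selects the
#' potentiation branch, otherwise the depression branch. Non-winner weights
#' are untouched.
#'
#' @param rule an [stdp_rule()].
#' @param input_wave the layer's actual input spike-wave (post-padding).
#' @param output_tp thresholded potentials the winners were selected from
#'   (kept for interface symmetry and validation).
#' @param output_wave the layer's output spike-wave.
#' @param winners data.frame from [get_k_winners()].
#' @param layer the [conv_layer()] to update.
#' @return the layer with updated weights.
#' @export
stdp_step <- function(rule, input_wave, output_tp, output_wave, winners,
                      layer) {
  stopifnot(inherits(rule, "stdp_rule"), inherits(layer, "conv_layer"))
  if (is.null(winners) || nrow(winners) == 0L) return(layer)
  d_in <- dim(input_wave)
  d_out <- dim(output_tp)
  kh <- layer$kernel_size[1L]; kw <- layer$kernel_size[2L]
  if (any(winners$feature < 1L | winners$feature > layer$out_features) ||
      any(winners$row < 1L | winners$row > d_out[3L]) ||
      any(winners$col < 1L | winners$col > d_out[4L]))
    stop("winner outside the output tensor bounds")
  pre_times <- wave_to_spike_times(input_wave)
  lb <- rule$lower_bound; ub <- rule$upper_bound
  for (i in seq_len(nrow(winners))) {
    f <- winners$feature[i]
    r <- winners$row[i]; c <- winners$col[i]
    t_i <- winners$step[i]
    t_j <- pre_times[, r:(r + kh - 1L), c:(c + kw - 1L), drop = FALSE]
    potentiate <- !is.na(t_j) & t_j <= t_i
    w <- array(layer$weights[f, , , ], dim = c(d_in[2L], kh, kw))
    rate <- ifelse(potentiate, rule$a_plus, rule$a_minus)
    if (rule$use_stabilizer) {
      w <- w + rate * (w - lb) * (ub - w)
    } else {
      w <- pmin(pmax(w + rate, lb), ub)
    }
    layer$weights[f, , , ] <- w
  }
  layer
}

#' Reward: apply the STDP side of an R-STDP pair
#'
#' Called when the network's decision matches the label. The forward
#' context must carry the data saved during the training forward pass;
#' with no winners (a silent stimulus) the call is a no-op.
#'
#' @param pair an [rstdp_pair()].
#' @param layer the [conv_layer()] under reinforcement.
#' @param context list with elements \code{input} (the layer's input
#'   spike-wave), \code{potentials} (thresholded output potentials),
#'   \code{output} (output spike-wave) and \code{winners}.
#' @return the updated layer.
#' @export
reward <- function(pair, layer, context) {
  stopifnot(inherits(pair, "rstdp_pair"))
  check_context(context)
  stdp_step(pair$stdp, context$input, context$potentials, context$output,
            context$winners, layer)
}

#' Punish: apply the anti-STDP side of an R-STDP pair
#'
#' Called when the decision mismatches the label; mirrors [reward()] with
#' the negated-rate rule.
#'
#' @inheritParams reward
#' @return the updated layer.
#' @export
punish <- function(pair, layer, context) {
  stopifnot(inherits(pair, "rstdp_pair"))
  check_context(context)
  stdp_step(pair$anti_stdp, context$input, context$potentials,
            context$output, context$winners, layer)
}

check_context <- function(context) {
  if (is.null(context) ||
      !all(c("input", "potentials", "output", "winners") %in%
             names(context)))
    stop("missing forward context: run a training forward pass first")
  invisible(TRUE)
}

#' Selectivity emergence under recurring-pattern stimulation
#'
#' Desk-scale replication of the classic result that a winner-take-all
#' STDP layer latches onto a spatio-temporal spike pattern that recurs
#' among noise: a single convolutional layer (one input channel, one
#' output location per feature) is exposed to a stream of stimuli in
#' which a fixed pattern - a random subset of input neurons firing at
#' fixed early time-steps - appears in a fraction of presentations, while
#' every other neuron (and every neuron on pure-noise trials) spikes at a
#' random step with probability \code{spike_prob}. After training, at
#' least one feature's weight vector should align with the pattern's
#' binary indicator.
#'
#' @param n_features number of competing features.
#' @param kernel_size input window side (input equals the receptive
#'   field, so each feature has exactly one output neuron).
#' @param t_max number of time-steps; pattern spikes occupy the first
#'   half.
#' @param presentations number of stimuli shown.
#' @param pattern_prob probability that a presentation contains the
#'   pattern.
#' @param spike_prob per-neuron spiking probability for background and
#'   noise-trial activity.
#' @param threshold firing threshold of the layer.
#' @param a_plus,a_minus STDP rates (stabilizer on, bounds [0, 1]).
#' @param seed integer seed for the pattern, the stimulus stream and the
#'   weight initialization.
#' @return list with \code{cosine} (the best feature's cosine similarity
#'   to the pattern indicator), \code{per_feature} cosines,
#'   \code{pattern} (binary matrix) and the trained \code{layer}.
#' @export
selectivity_experiment <- function(n_features = 4L, kernel_size = 5L,
                                   t_max = 10L, presentations = 400L,
                                   pattern_prob = 0.7, spike_prob = 0.5,
                                   threshold = 9, a_plus = 0.05,
                                   a_minus = -0.0375, seed = 1L) {
  with_preserved_rng({
    set.seed(as.integer(seed))
    k2 <- kernel_size^2
    pattern <- matrix(stats::runif(k2) < 0.5, kernel_size, kernel_size)
    early <- max(1L, t_max %/% 2L)
    pattern_times <- matrix(sample.int(early, k2, replace = TRUE) - 1L,
                            kernel_size, kernel_size)
    layer <- conv_layer(1L, n_features, kernel_size,
                        init_mean = 0.5, init_sd = 0.05)
    rule <- stdp_rule(a_plus, a_minus, 0, 1, use_stabilizer = TRUE)
    for (p in seq_len(presentations)) {
      noise_times <- matrix(sample.int(t_max, k2, replace = TRUE) - 1L,
                            kernel_size, kernel_size)
      noise_times[stats::runif(k2) >= spike_prob] <- NA_integer_
      times <- noise_times
      if (stats::runif(1) < pattern_prob) times[pattern] <-
        pattern_times[pattern]
      wave <- spike_times_to_wave(
        array(times, dim = c(1L, kernel_size, kernel_size)), t_max)
      pot <- conv_forward(wave, layer)
      tp <- threshold_op(pot, threshold)
      winners <- get_k_winners(tp, k = 1L, inhibition_radius = 0L)
      layer <- stdp_step(rule, wave, tp, fire(pot, threshold), winners,
                         layer)
    }
    ind <- as.vector(pattern) + 0
    cosines <- vapply(seq_len(n_features), function(f) {
      w <- as.vector(layer$weights[f, 1L, , ])
      sum(w * ind) / (sqrt(sum(w^2)) * sqrt(sum(ind^2)))
    }, numeric(1))
    list(cosine = max(cosines), per_feature = cosines,
         pattern = pattern, layer = layer)
  })
}
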