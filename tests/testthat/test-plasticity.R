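# minimal one-winner setting: 1 input channel, input window == kernel
stdp_fixture <- function(pre_times, t_i, weight, rule, t_max = 4L) {
  k <- nrow(pre_times)
  layer <- conv_layer(1L, 1L, k)
  layer$weights[1, 1, , ] <- weight
  input <- spike_times_to_wave(array(pre_times, dim = c(1L, k, k)), t_max)
  tp <- array(0, dim = c(t_max, 1L, 1L, 1L))
  tp[(t_i + 1L):t_max, 1, 1, 1] <- 1
  winners <- data.frame(feature = 1L, row = 1L, col = 1L, step = t_i,
                        potential = 1)
  stdp_step(rule, input, tp, fire(tp, 0.5), winners, layer)
}

test_that("the stabilized update follows the two-branch weight rule", {
  rule <- stdp_rule(0.1, -0.05, 0, 1, use_stabilizer = TRUE)
  # pre fires before post: dW = A+ * (W - LB)(UB - W) = 0.1 * 0.5 * 0.5
  pre <- matrix(0L, 1, 1)
  out <- stdp_fixture(pre, t_i = 2L, weight = 0.5, rule = rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.5 + 0.025)
  # simultaneous spikes potentiate (T_j <= T_i)
  out <- stdp_fixture(matrix(2L, 1, 1), 2L, 0.5, rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.525)
  # pre after post, and pre silent, both depress
  out <- stdp_fixture(matrix(3L, 1, 1), 2L, 0.5, rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.5 - 0.0125)
  out <- stdp_fixture(matrix(NA_integer_, 1, 1), 2L, 0.5, rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.5 - 0.0125)
})

test_that("bounds are fixed points with the stabilizer on", {
  rule <- stdp_rule(0.2, -0.2, 0.2, 0.8, use_stabilizer = TRUE)
  for (w0 in c(0.2, 0.8)) {
    out <- stdp_fixture(matrix(0L, 1, 1), 1L, w0, rule)
    expect_equal(out$weights[1, 1, 1, 1], w0)
  }
})

test_that("clamped mode keeps weights inside the bounds", {
  rule <- stdp_rule(0.3, -0.3, 0.2, 0.8, use_stabilizer = FALSE)
  out <- stdp_fixture(matrix(0L, 1, 1), 1L, 0.7, rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.8)   # 0.7 + 0.3 clamps to UB
  out <- stdp_fixture(matrix(NA_integer_, 1, 1), 1L, 0.3, rule)
  expect_equal(out$weights[1, 1, 1, 1], 0.2)   # 0.3 - 0.3 clamps to LB
})

test_that("stabilized weights started inside the bounds never escape", {
  set.seed(51)
  rule <- stdp_rule(0.08, -0.06, 0.1, 0.9, use_stabilizer = TRUE)
  layer <- conv_layer(1L, 2L, 3L, init_mean = 0.5, init_sd = 0.08)
  for (i in 1:150) {
    wave <- random_wave(1L, 3L, 3L, 4L, p_silent = 0.4)
    pot <- conv_forward(wave, layer)
    tp <- threshold_op(pot, 0.4)
    winners <- get_k_winners(tp, 1L)
    layer <- stdp_step(rule, wave, tp, fire(pot, 0.4), winners, layer)
    expect_true(all(layer$weights >= 0.1 & layer$weights <= 0.9))
  }
})

test_that("only winner receptive fields change", {
  set.seed(52)
  rule <- stdp_rule(0.1, -0.05)
  layer <- conv_layer(2L, 3L, 2L)
  wave <- random_wave(2L, 5L, 5L, 3L, p_silent = 0.2)
  pot <- conv_forward(wave, layer)
  tp <- threshold_op(pot, 1)
  winners <- get_k_winners(tp, 1L)
  out <- stdp_step(rule, wave, tp, fire(pot, 1), winners, layer)
  changed <- which(out$weights != layer$weights, arr.ind = TRUE)
  expect_true(all(changed[, 1] == winners$feature[1]))
  # no winners -> no change; bad winner -> consistency error
  none <- get_k_winners(array(0, dim = dim(tp)), 1L)
  expect_identical(stdp_step(rule, wave, tp, fire(pot, 1), none, layer),
                   layer)
  bad <- data.frame(feature = 9L, row = 1L, col = 1L, step = 0L,
                    potential = 1)
  expect_error(stdp_step(rule, wave, tp, fire(pot, 1), bad, layer),
               "bounds")
})

test_that("reward and punish mirror each other and can cancel", {
  set.seed(53)
  pair <- rstdp_pair(stdp_rule(0.04, -0.03, 0, 1, use_stabilizer = FALSE),
                     stdp_rule(-0.04, 0.03, 0, 1, use_stabilizer = FALSE))
  layer <- conv_layer(1L, 2L, 3L, init_mean = 0.5, init_sd = 0.02)
  wave <- random_wave(1L, 3L, 3L, 4L, p_silent = 0.3)
  pot <- conv_forward(wave, layer)
  tp <- threshold_op(pot, 0.4)
  ctx <- list(input = wave, potentials = tp, output = fire(pot, 0.4),
              winners = get_k_winners(tp, 1L))
  up <- reward(pair, layer, ctx)
  down <- punish(pair, layer, ctx)
  expect_equal(up$weights - layer$weights,
               -(down$weights - layer$weights), tolerance = 1e-12)
  # alternating reward/punish with equal magnitudes returns to start
  expect_equal(punish(pair, up, ctx)$weights, layer$weights,
               tolerance = 1e-12)
  # two rewards compose sequentially
  expect_equal(reward(pair, up, ctx)$weights - up$weights,
               up$weights - layer$weights, tolerance = 1e-12)
  # silent context is a no-op; missing context errors
  silent_ctx <- ctx
  silent_ctx$winners <- ctx$winners[0, ]
  expect_identical(reward(pair, layer, silent_ctx), layer)
  expect_error(reward(pair, layer, NULL), "context")
  expect_error(rstdp_pair(stdp_rule(0.1, -0.1),
                          stdp_rule(0.1, -0.1)), "opposite sign")
})

test_that("a recurring pattern among noise is learned by one feature", {
  res <- selectivity_experiment(presentations = 400L, seed = 1L)
  expect_gt(res$cosine, 0.8)
  expect_true(all(res$layer$weights >= 0 & res$layer$weights <= 1))
})
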