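test_that("spiking convolution matches the per-time-step oracle", {
  set.seed(31)
  for (i in 1:10) {
    f_in <- sample(1:3, 1); f_out <- sample(1:4, 1)
    kh <- sample(1:3, 1); kw <- sample(1:3, 1)
    h <- sample(kh:7, 1); w <- sample(kw:7, 1)
    t_max <- sample(1:5, 1)
    wave <- random_wave(f_in, h, w, t_max)
    layer <- conv_layer(f_in, f_out, c(kh, kw))
    expect_equal(conv_forward(wave, layer), oracle_conv(wave, layer),
                 tolerance = 1e-10)
  }
})

test_that("convolution obeys the valid-mode shape law and input checks", {
  # 5x5 single-channel wave, 3 steps, 3x3 kernel -> 3-step 3x3 potentials
  wave <- random_wave(1L, 5L, 5L, 3L)
  layer <- conv_layer(1L, 4L, 3L)
  p <- conv_forward(wave, layer)
  expect_equal(dim(p), c(3L, 4L, 3L, 3L))
  expect_equal(sum(conv_forward(array(0, dim = c(3, 1, 5, 5)), layer)), 0)
  expect_error(conv_forward(random_wave(2L, 5L, 5L, 3L), layer),
               "features")
  expect_error(conv_forward(random_wave(1L, 2L, 2L, 3L), layer),
               "kernel larger")
})

test_that("weight initialization is a seeded normal draw per layer", {
  set.seed(5); a <- conv_layer(2L, 3L, 3L, init_mean = 0.4, init_sd = 0.1)
  set.seed(5); b <- conv_layer(2L, 3L, 3L, init_mean = 0.4, init_sd = 0.1)
  expect_identical(a$weights, b$weights)
  expect_equal(mean(a$weights), 0.4, tolerance = 0.1)
  expect_equal(dim(a$weights), c(3L, 2L, 3L, 3L))
})

test_that("padding adds silent border neurons only", {
  wave <- random_wave(2L, 2L, 2L, 3L)
  out <- pad_wave(wave, c(1L, 1L))
  expect_equal(dim(out), c(3L, 2L, 4L, 4L))
  expect_true(validate_wave(out))
  expect_equal(out[, , 2:3, 2:3], wave)
  expect_equal(sum(out), sum(wave))
  expect_identical(pad_wave(wave, 0L), wave)
})

test_that("pooling matches the naive window-max oracle", {
  set.seed(32)
  for (i in 1:10) {
    x <- random_potentials(f = sample(1:3, 1), h = sample(3:8, 1),
                           w = sample(3:8, 1), t_max = sample(2:5, 1))
    spec <- pool_spec(sample(1:3, 1), stride = sample(1:3, 1),
                      padding = sample(0:1, 1))
    if (dim(x)[3] + 2 * spec$padding[1] < spec$stride[1] ||
        dim(x)[4] + 2 * spec$padding[2] < spec$stride[2]) next
    expect_equal(pool(x, spec), oracle_pool(x, spec))
  }
})

test_that("pooling a spike-wave keeps the earliest spike per window", {
  expect_equal(dim(pool(random_wave(1L, 6L, 6L, 2L), pool_spec(2L)))[3:4],
               c(3L, 3L))
  g <- array(NA_integer_, dim = c(1L, 2L, 2L))
  g[1, 1, 1] <- 3L; g[1, 2, 2] <- 1L
  w <- spike_times_to_wave(g, 4L)
  pw <- pool(w, pool_spec(2L))
  expect_equal(wave_to_spike_times(pw)[1, 1, 1], 1L)
  # commutation: pooling then first-spike == per-window min of spike times
  set.seed(33)
  for (i in 1:5) {
    w <- random_wave(2L, 6L, 6L, 4L)
    spec <- pool_spec(2L)
    a <- wave_to_spike_times(pool(w, spec))
    t <- wave_to_spike_times(w)
    t[is.na(t)] <- .Machine$integer.max
    b <- array(NA_integer_, dim = dim(a))
    for (f in 1:2) for (r in 1:3) for (c in 1:3) {
      m <- min(t[f, (2 * r - 1):(2 * r), (2 * c - 1):(2 * c)])
      b[f, r, c] <- if (m == .Machine$integer.max) NA_integer_ else m
    }
    expect_identical(a, b)
    expect_true(validate_wave(pool(w, spec)))
  }
})

test_that("firing is a strict threshold crossing with a single spike", {
  p <- array(c(0.4, 0.8, 1.2), dim = c(3L, 1L, 1L, 1L))
  expect_equal(fire(p, 0.5)[, 1, 1, 1], c(0, 1, 1))
  expect_equal(sum(fire(p, 99)), 0)
  expect_equal(sum(fire(p, -1e9)), 3)
  both <- fire(p, 0.5, return_thresholded = TRUE)
  expect_equal(both$potentials[, 1, 1, 1], c(0, 0.8, 1.2))
  # fire o conv of a valid wave is a valid wave for any threshold
  set.seed(34)
  wave <- random_wave(2L, 6L, 6L, 4L)
  layer <- conv_layer(2L, 3L, 3L)   # near-certainly positive weights
  pot <- conv_forward(wave, layer)
  for (thr in c(-1, 0, 0.5, 2, 10))
    expect_true(validate_wave(fire(pot, thr)))
})

test_that("infinite-threshold firing spikes only at the last step", {
  p <- random_potentials(2L, 3L, 3L, 4L)
  p[4, 1, 1, 1] <- 0
  out <- fire_infinite(p, return_thresholded = TRUE)
  expect_equal(sum(out$spikes[1:3, , , ]), 0)
  expect_equal(out$spikes[4, , , ], (p[4, , , ] != 0) + 0)
  expect_equal(out$spikes[4, 1, 1, 1], 0)
  expect_equal(sum(out$potentials[1:3, , , ]), 0)
  expect_equal(out$potentials[4, , , ], p[4, , , ])
  expect_true(validate_wave(out$spikes))
  expect_equal(sum(fire_infinite(array(0, dim = c(3, 1, 2, 2)))), 0)
})

test_that("threshold_op zeroes exactly the sub-threshold entries", {
  p <- random_potentials(2L, 4L, 4L, 3L)
  expect_equal(threshold_op(p, min(p) - 1), p)
  expect_equal(sum(threshold_op(p, max(p) + 1)), 0)
  thr <- stats::median(p)
  tp <- threshold_op(p, thr)
  expect_equal(tp, ifelse(p < thr, 0, p),
               ignore_attr = FALSE)
})
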