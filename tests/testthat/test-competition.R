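test_that("winner selection puts spike time before potential", {
  tp <- array(0, dim = c(3L, 2L, 1L, 2L))
  tp[, 1, 1, 1] <- c(0.6, 0.6, 0.6)     # fires step 0, small potential
  tp[, 2, 1, 2] <- c(0, 0, 9)           # fires step 2, huge potential
  w <- get_k_winners(tp, k = 1L)
  expect_equal(w$feature, 1L)
  expect_equal(w$step, 0L)
  # same step: larger final potential wins
  tp2 <- array(0, dim = c(2L, 2L, 1L, 1L))
  tp2[, 1, 1, 1] <- c(1, 1); tp2[, 2, 1, 1] <- c(2, 2)
  expect_equal(get_k_winners(tp2, 1L)$feature, 2L)
  # full ties resolve to the lexicographically lowest coordinate
  tp3 <- array(1, dim = c(2L, 2L, 2L, 2L))
  w3 <- get_k_winners(tp3, 1L)
  expect_equal(unlist(w3[1, 1:3]), c(feature = 1L, row = 1L, col = 1L))
})

test_that("winner selection matches the exhaustive oracle", {
  set.seed(41)
  for (i in 1:30) {
    t_max <- sample(2:5, 1)
    tp <- threshold_op(random_potentials(sample(1:4, 1), sample(2:6, 1),
                                         sample(2:6, 1), t_max),
                       runif(1, 0.5, 3))
    k <- sample(1:4, 1)
    radius <- sample(0:2, 1)
    got <- get_k_winners(tp, k, radius)
    want <- oracle_winners(tp, k, radius)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0)
      expect_equal(as.list(got), as.list(want), ignore_attr = TRUE)
  }
})

test_that("winner lists are deterministic, feature-distinct and ordered", {
  set.seed(42)
  tp <- threshold_op(random_potentials(4L, 5L, 5L, 4L), 1)
  a <- get_k_winners(tp, 4L, 1L)
  b <- get_k_winners(tp, 4L, 1L)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$feature), 0L)
  expect_true(all(diff(a$step) >= 0))
  same <- which(diff(a$step) == 0)
  expect_true(all(a$potential[same] >= a$potential[same + 1L]))
  # spatial separation: no two winners within each other's radius square
  if (nrow(a) > 1) {
    for (i in 1:(nrow(a) - 1)) for (j in (i + 1):nrow(a)) {
      expect_true(max(abs(a$row[i] - a$row[j]),
                      abs(a$col[i] - a$col[j])) > 1)
    }
  }
  # a lone firing neuron is the sole winner
  solo <- array(0, dim = c(2L, 2L, 3L, 3L)); solo[2, 1, 2, 2] <- 1.5
  expect_equal(nrow(get_k_winners(solo, 5L, 1L)), 1L)
  expect_error(get_k_winners(solo, 0L), "positive")
})

test_that("lateral inhibition masks cut square holes but spare winners", {
  w <- data.frame(feature = 2L, row = 2L, col = 2L, step = 0L,
                  potential = 1)
  m <- lateral_inhibition_mask(c(3L, 4L, 4L), w, 1L)
  expect_equal(m[2, 2, 2], 1)           # winner's own cell survives
  expect_equal(sum(m[, 1:3, 1:3] == 0), 3 * 9 - 1)
  expect_true(all(m[, 4, ] == 1))
  # radius 0 removes nothing but keeps shape
  m0 <- lateral_inhibition_mask(c(2L, 3L, 3L), w, 0L)
  expect_equal(sum(m0 == 0), 1)         # only the other feature's cell
  # distant winners punch independent holes
  w2 <- rbind(w, data.frame(feature = 1L, row = 4L, col = 4L, step = 1L,
                            potential = 0.5))
  m2 <- lateral_inhibition_mask(c(3L, 6L, 6L), w2, 1L)
  expect_equal(m2[1, 4, 4], 1)
  expect_equal(m2[2, 4, 4], 0)
})

test_that("pointwise inhibition keeps one feature per location", {
  tp <- array(0, dim = c(3L, 2L, 1L, 1L))
  tp[, 1, 1, 1] <- c(0, 1, 1)   # fires step 1
  tp[, 2, 1, 1] <- c(0, 0, 1)   # fires step 2
  out <- pointwise_inhibition(tp)
  expect_equal(wave_to_spike_times(out)[1, 1, 1], 1L)
  expect_true(is.na(wave_to_spike_times(out)[2, 1, 1]))
  # single feature passes through as its spike wave
  single <- array(c(0, 0.5, 0.7), dim = c(3L, 1L, 1L, 1L))
  expect_equal(wave_to_spike_times(pointwise_inhibition(single))[1, 1, 1],
               1L)
  set.seed(43)
  for (i in 1:15) {
    tp <- threshold_op(random_potentials(sample(2:4, 1), 4L, 4L, 4L),
                       runif(1, 1, 3))
    got <- pointwise_inhibition(tp)
    expect_equal(got, oracle_pointwise(tp))
    expect_true(validate_wave(got))
    expect_true(all(apply(got[4, , , , drop = FALSE], c(3, 4), sum) <= 1))
  }
})

test_that("feature inhibition silences exactly the selected maps", {
  w <- random_wave(3L, 4L, 4L, 3L)
  expect_identical(feature_inhibition(w, integer(0)), w)
  expect_equal(sum(feature_inhibition(w, 1:3)), 0)
  one <- feature_inhibition(w, 1L)
  expect_equal(sum(one[, 1, , ]), 0)
  expect_equal(one[, 2:3, , ], w[, 2:3, , ])
  expect_error(feature_inhibition(w, 4L), "out of range")
})

test_that("feature suppression can be relaxed to spatial-only", {
  tp <- array(0, dim = c(2L, 1L, 1L, 5L))
  tp[, 1, 1, 1] <- c(1, 1)
  tp[, 1, 1, 5] <- c(0, 2)
  w <- get_k_winners(tp, 2L, inhibition_radius = 1L,
                     suppress_feature = FALSE)
  expect_equal(w$feature, c(1L, 1L))      # one map, two distant winners
  expect_equal(nrow(get_k_winners(tp, 2L, 1L)), 1L)  # default: map out
})
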