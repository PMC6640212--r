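#' Convert a grid of first-spike times into an accumulative spike-wave tensor
#'
#' A stimulus for a time-to-first-spike network is a grid of neurons, each of
#' which fires at most once, at a discrete time-step \code{t} in
#' \code{0, ..., t_max - 1}, or never fires (\code{NA}). The accumulative
#' spike-wave tensor redundantly repeats every spike at all later steps:
#' entry \code{[t+1, f, r, c]} is 1 exactly when the neuron at position
#' \code{(r, c)} of feature map \code{f} has fired at step \code{t} or
#' earlier. This redundancy is what allows every time-step to be processed
#' simultaneously by one tensor operation downstream.
#'
#' @param times integer 3-D array of shape (features, rows, cols) holding
#'   each neuron's first-spike step, 0-based (step 0 is the earliest bin).
#'   \code{NA} means the neuron never spikes.
#' @param t_max positive integer, the number of discrete time-steps.
#' @return a binary array of shape \code{(t_max, F, H, W)} that is
#'   non-decreasing along its first (time) axis.
#' @examples
#' g <- array(c(0L, 2L, NA, 1L), dim = c(1, 2, 2))
#' w <- spike_times_to_wave(g, t_max = 4)
#' w[, 1, 1, 1]  # spikes at step 0: 1 1 1 1
#' w[, 1, 2, 1]  # spikes at step 2: 0 0 1 1
#' @seealso [wave_to_spike_times()], [validate_wave()]
#' @export
spike_times_to_wave <- function(times, t_max) {
  if (!is.array(times) || length(dim(times)) != 3L)
    stop("`times` must be a 3-D array (features, rows, cols)")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < 1)
    stop("`t_max` must be a positive integer")
  t_max <- as.integer(t_max)
  tv <- as.vector(times)
  finite <- !is.na(tv)
  if (any(tv[finite] < 0L) || any(tv[finite] != floor(tv[finite])))
    stop("spike times must be non-negative integers or NA")
  if (any(tv[finite] >= t_max))
    stop("spike time out of range: found step >= t_max (", t_max, ")")
  d <- dim(times)
  # column t of a (n_neurons x t_max) matrix is the slice at step t-1
  steps <- matrix(rep(seq_len(t_max) - 1L, each = length(tv)), ncol = t_max)
  acc <- steps >= tv[row(steps)]
  acc[is.na(acc)] <- FALSE
  wave <- array(0, dim = c(t_max, d))
  # acc is (neuron, t); wave wants (t, f, r, c) with neuron = (f, r, c)
  wave[] <- as.numeric(t(acc))
  wave
}

#' Recover first-spike times from an accumulative spike-wave tensor
#'
#' The inverse of [spike_times_to_wave()]: each neuron's spike time is the
#' earliest step at which its accumulative column is 1; an all-zero column
#' means the neuron never spikes (\code{NA}).
#'
#' @param wave a valid accumulative spike-wave tensor, shape (T, F, H, W).
#' @return integer array of shape (F, H, W) with 0-based first-spike steps,
#'   \code{NA} where no spike occurs.
#' @export
wave_to_spike_times <- function(wave) {
  if (!validate_wave(wave))
    stop("`wave` is not a valid spike-wave tensor (binary, time-monotone, 4-D)")
  d <- dim(wave)
  t_max <- d[1L]
  # accumulative => number of ones in a column is t_max - first_spike
  counts <- colSums(matrix(wave, nrow = t_max))
  times <- t_max - as.integer(counts)
  times[counts == 0] <- NA_integer_
  array(times, dim = d[-1L])
}

#' Test whether a tensor is a valid accumulative spike-wave
#'
#' Valid means: 4-D, every entry exactly 0 or 1, and non-decreasing along the
#' time (first) axis, so each neuron fires at most once and stays "on".
#'
#' @param wave any object.
#' @return \code{TRUE} or \code{FALSE}; never throws.
#' @export
validate_wave <- function(wave) {
  if (!is.array(wave) || length(dim(wave)) != 4L) return(FALSE)
  v <- as.vector(wave)
  if (anyNA(v) || !all(v == 0 | v == 1)) return(FALSE)
  t_max <- dim(wave)[1L]
  if (t_max > 1L) {
    m <- matrix(wave, nrow = t_max)
    if (any(m[-1L, , drop = FALSE] < m[-t_max, , drop = FALSE])) return(FALSE)
  }
  TRUE
}
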