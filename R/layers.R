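#' Spiking convolutional layer
#'
#' Holds the 4-D synaptic weight tensor (out-features x in-features x
#' kernel-rows x kernel-cols) of a spiking convolution. Weights are drawn
#' from a normal distribution whose mean and standard deviation are set per
#' layer; with a mean well inside (0, 1) and a small spread, early potentials
#' are unselective and selectivity emerges through plasticity.
#'
#' @param in_features,out_features positive integer channel counts.
#' @param kernel_size integer length-1 or length-2 (rows, cols) kernel size.
#' @param init_mean,init_sd mean and standard deviation of the normal weight
#'   initializer.
#' @return an object of class \code{"conv_layer"}.
#' @export
conv_layer <- function(in_features, out_features, kernel_size,
                       init_mean = 0.8, init_sd = 0.05) {
  if (in_features < 1 || out_features < 1)
    stop("feature counts must be positive")
  kernel_size <- as.integer(rep(kernel_size, length.out = 2L))
  if (any(kernel_size < 1)) stop("kernel size must be positive")
  w <- array(stats::rnorm(out_features * in_features * prod(kernel_size),
                          mean = init_mean, sd = init_sd),
             dim = c(out_features, in_features, kernel_size))
  structure(list(weights = w,
                 in_features = as.integer(in_features),
                 out_features = as.integer(out_features),
                 kernel_size = kernel_size,
                 init_mean = init_mean, init_sd = init_sd),
            class = "conv_layer")
}

#' @export
print.conv_layer <- function(x, ...) {
  cat("conv_layer:", x$in_features, "->", x$out_features,
      "features, kernel", paste(x$kernel_size, collapse = "x"),
      "\n")
  invisible(x)
}

#' Spiking convolution forward pass
#'
#' Applies a valid (no padding), stride-1, 2-D cross-correlation of the
#' layer's weights with every time-slice of an accumulative spike-wave
#' tensor at once. Because the wave is accumulative, the result at step t is
#' the total membrane potential contributed by all input spikes emitted at
#' steps <= t: the potentials tensor is accumulative too. Output spatial
#' size is \code{(H_in - K_h + 1) x (W_in - K_w + 1)}.
#'
#' @param wave spike-wave tensor (T, F_in, H, W).
#' @param layer a [conv_layer()] with matching \code{F_in}.
#' @return potentials array (T, F_out, H_out, W_out).
#' @export
conv_forward <- function(wave, layer) {
  stopifnot(inherits(layer, "conv_layer"))
  d <- dim(wave)
  if (is.null(d) || length(d) != 4L)
    stop("`wave` must be a 4-D array (time, feature, row, col)")
  t_max <- d[1L]; f_in <- d[2L]; h_in <- d[3L]; w_in <- d[4L]
  kh <- layer$kernel_size[1L]; kw <- layer$kernel_size[2L]
  if (f_in != layer$in_features)
    stop("input has ", f_in, " features but layer expects ",
         layer$in_features)
  if (h_in < kh || w_in < kw)
    stop("kernel larger than input (valid convolution impossible)")
  h_out <- h_in - kh + 1L
  w_out <- w_in - kw + 1L
  f_out <- layer$out_features
  # im2col: one linear-index table shared by all time slices.
  # output positions, row index varying fastest
  r0 <- rep(seq_len(h_out), times = w_out) - 1L
  c0 <- rep(seq_len(w_out), each = h_out) - 1L
  base <- f_in * (r0 + h_in * c0)                      # length O
  # synapse offsets ordered (f_in fastest, then k_row, then k_col) to match
  # the column-major flattening of the (F_out, F_in, K_h, K_w) weights
  fi <- rep(seq_len(f_in), times = kh * kw)
  kr <- rep(rep(seq_len(kh), each = f_in), times = kw) - 1L
  kc <- rep(seq_len(kw), each = f_in * kh) - 1L
  off <- fi + f_in * (kr + h_in * kc)                  # length S
  idx <- outer(base, off, "+")                         # O x S
  wmat <- t(matrix(layer$weights, nrow = f_out))       # S x F_out
  m <- matrix(wave, nrow = t_max)                      # T x (F_in*H*W)
  pot <- array(0, dim = c(t_max, f_out, h_out, w_out))
  for (t in seq_len(t_max)) {
    patches <- matrix(m[t, ][idx], nrow = length(base))  # O x S
    res <- patches %*% wmat                              # O x F_out
    pot[t, , , ] <- aperm(array(res, dim = c(h_out, w_out, f_out)),
                          c(3L, 1L, 2L))
  }
  pot
}

#' Zero-pad the spatial axes of a spike-wave tensor
#'
#' Padding neurons never spike, so padded entries are 0 at every time-step
#' and the result is still a valid accumulative wave. Feeding each
#' convolutional layer the padded output of the previous one avoids
#' information loss at the boundaries.
#'
#' @param wave spike-wave (or potentials) tensor (T, F, H, W).
#' @param padding length-1 or length-2 non-negative integer (rows, cols).
#' @return tensor of shape (T, F, H + 2p_h, W + 2p_w).
#' @export
pad_wave <- function(wave, padding) {
  d <- dim(wave)
  if (is.null(d) || length(d) != 4L)
    stop("`wave` must be a 4-D array")
  padding <- as.integer(rep(padding, length.out = 2L))
  if (any(padding < 0)) stop("`padding` must be non-negative")
  if (all(padding == 0L)) return(wave)
  out <- array(0, dim = c(d[1L], d[2L],
                          d[3L] + 2L * padding[1L],
                          d[4L] + 2L * padding[2L]))
  out[, , padding[1L] + seq_len(d[3L]), padding[2L] + seq_len(d[4L])] <- wave
  out
}

#' Pooling specification
#'
#' @param window length-1 or length-2 positive pooling window (rows, cols).
#' @param stride strides; defaults to the window (non-overlapping pooling).
#' @param padding non-negative zero-padding of the spatial axes.
#' @return an object of class \code{"pool_spec"}.
#' @export
pool_spec <- function(window, stride = window, padding = 0L) {
  window <- as.integer(rep(window, length.out = 2L))
  stride <- as.integer(rep(stride, length.out = 2L))
  padding <- as.integer(rep(padding, length.out = 2L))
  if (any(window < 1)) stop("pooling window must be positive")
  if (any(stride < 1)) stop("pooling stride must be positive")
  if (any(padding < 0)) stop("pooling padding must be non-negative")
  structure(list(window = window, stride = stride, padding = padding),
            class = "pool_spec")
}

#' Max-pooling over spike-wave or potentials tensors
#'
#' Per time-step and feature, takes the maximum over each pooling window.
#' On an accumulative spike-wave the window maximum of binary columns IS the
#' earliest spike in the window, so spike-wave in gives a valid spike-wave
#' out; on potentials it extracts the maximum potential. The output spatial
#' size is \code{floor((H_in + 2 D_h) / R_h) x floor((W_in + 2 D_w) / R_w)};
#' windows that would extend past the padded border are truncated there so
#' this size is always realizable.
#'
#' @param x 4-D tensor (T, F, H, W), spike-wave or potentials.
#' @param spec a [pool_spec()].
#' @return pooled tensor of the same kind as the input.
#' @export
pool <- function(x, spec) {
  stopifnot(inherits(spec, "pool_spec"))
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("`x` must be a 4-D array")
  ph <- spec$window[1L]; pw <- spec$window[2L]
  rh <- spec$stride[1L]; rw <- spec$stride[2L]
  dh <- spec$padding[1L]; dw <- spec$padding[2L]
  hp <- d[3L] + 2L * dh
  wp <- d[4L] + 2L * dw
  h_out <- hp %/% rh
  w_out <- wp %/% rw
  if (h_out < 1L || w_out < 1L)
    stop("pooling window/stride too large for the padded input")
  xp <- x
  if (dh > 0L || dw > 0L) {
    xp <- array(0, dim = c(d[1L], d[2L], hp, wp))
    xp[, , dh + seq_len(d[3L]), dw + seq_len(d[4L])] <- x
  }
  out <- array(0, dim = c(d[1L], d[2L], h_out, w_out))
  nf <- d[1L] * d[2L]
  for (i in seq_len(h_out)) {
    rows <- ((i - 1L) * rh + 1L):min((i - 1L) * rh + ph, hp)
    for (j in seq_len(w_out)) {
      cols <- ((j - 1L) * rw + 1L):min((j - 1L) * rw + pw, wp)
      win <- matrix(xp[, , rows, cols, drop = FALSE], nrow = nf)
      out[, , i, j] <- apply(win, 1L, max)
    }
  }
  out
}

#' Convert potentials into spikes by thresholding
#'
#' A neuron fires as soon as its accumulated potential strictly exceeds the
#' threshold; on an accumulative (non-decreasing) potentials tensor the
#' resulting wave is 1 from the first crossing onward, i.e. at most one
#' spike per neuron.
#'
#' @param p potentials tensor (T, F, H, W).
#' @param threshold finite firing threshold.
#' @param return_thresholded if \code{TRUE}, also return the thresholded
#'   potentials (see [threshold_op()]) alongside the spikes.
#' @return the spike-wave array, or (with \code{return_thresholded}) a list
#'   with elements \code{spikes} and \code{potentials}.
#' @export
fire <- function(p, threshold, return_thresholded = FALSE) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  spikes <- (p > threshold) + 0
  if (return_thresholded)
    list(spikes = spikes, potentials = threshold_op(p, threshold))
  else spikes
}

#' Infinite-threshold firing for the decision layer
#'
#' With an infinite threshold no neuron ever crosses it; instead, every
#' neuron with a non-zero potential at the final time-step emits its single
#' spike there. The returned thresholded potentials are zero at every step
#' before the last, so downstream winner selection sees only final-step
#' activity.
#'
#' @param p potentials tensor (T, F, H, W).
#' @param return_thresholded if \code{TRUE}, also return the potentials with
#'   all pre-final time-steps zeroed (the in-place reading).
#' @return spike-wave array, or a list \code{spikes} / \code{potentials}.
#' @export
fire_infinite <- function(p, return_thresholded = FALSE) {
  d <- dim(p)
  if (is.null(d) || length(d) != 4L)
    stop("`p` must be a 4-D array")
  t_max <- d[1L]
  spikes <- array(0, dim = d)
  spikes[t_max, , , ] <- (p[t_max, , , ] != 0) + 0
  if (return_thresholded) {
    tp <- array(0, dim = d)
    tp[t_max, , , ] <- p[t_max, , , ]
    list(spikes = spikes, potentials = tp)
  } else spikes
}

#' Zero out sub-threshold potentials
#'
#' Entries strictly below the threshold become 0; the rest are unchanged.
#' The result ("thresholded potentials") is what winner-take-all selection
#' consumes: a zero means the neuron never reached threshold.
#'
#' @param p potentials tensor.
#' @param threshold finite threshold.
#' @return tensor of the same shape.
#' @export
threshold_op <- function(p, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  p[p < threshold] <- 0
  p
}
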