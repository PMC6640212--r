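#' Pack filter kernels into a multi-channel filter bank
#'
#' A filter bank turns one grayscale image into a multi-channel intensity
#' map, one channel per kernel. Kernels of different window sizes are
#' zero-padded up to the largest window so the bank applies them as a single
#' multi-channel kernel and all channels share one spatial geometry.
#'
#' @param kernels list of odd square numeric matrices (e.g. from
#'   [make_dog_kernel()] / [make_gabor_kernel()]).
#' @param padding non-negative integer zero-padding applied to the image
#'   before filtering; \code{floor(window/2)} preserves the spatial size.
#' @param clip_threshold responses strictly below this value are set to 0
#'   (sub-threshold contrast produces no spikes downstream).
#' @return an object of class \code{"filter_bank"}.
#' @export
filter_bank <- function(kernels, padding = 0L, clip_threshold = 0) {
  if (!is.list(kernels) || length(kernels) == 0L)
    stop("`kernels` must be a non-empty list of matrices")
  for (k in kernels) {
    if (!is.matrix(k) || nrow(k) != ncol(k) || nrow(k) %% 2 != 1)
      stop("every kernel must be an odd square matrix")
  }
  if (padding < 0) stop("`padding` must be non-negative")
  size <- max(vapply(kernels, nrow, integer(1)))
  kernels <- lapply(kernels, function(k) {
    if (nrow(k) == size) return(k)
    pad <- (size - nrow(k)) %/% 2L
    out <- matrix(0, size, size)
    out[pad + seq_len(nrow(k)), pad + seq_len(ncol(k))] <- k
    out
  })
  structure(list(kernels = kernels, window_size = size,
                 padding = as.integer(padding),
                 clip_threshold = clip_threshold),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("filter_bank:", length(x$kernels), "kernel(s), window",
      x$window_size, "x", x$window_size, ", padding", x$padding,
      ", clip threshold", x$clip_threshold, "\n")
  invisible(x)
}

# valid-mode 2-D cross-correlation (no kernel flip)
cross_correlate2d <- function(image, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  h_out <- nrow(image) - kh + 1L
  w_out <- ncol(image) - kw + 1L
  if (h_out < 1L || w_out < 1L)
    stop("image smaller than the kernel window")
  out <- matrix(0, h_out, w_out)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (kernel[i, j] == 0) next
      out <- out + kernel[i, j] *
        image[i:(i + h_out - 1L), j:(j + w_out - 1L)]
    }
  }
  out
}

pad_matrix <- function(m, padding, value = 0) {
  if (padding == 0L) return(m)
  out <- matrix(value, nrow(m) + 2L * padding, ncol(m) + 2L * padding)
  out[padding + seq_len(nrow(m)), padding + seq_len(ncol(m))] <- m
  out
}

#' Apply a filter bank to a grayscale image
#'
#' Zero-pads the image by the bank's padding, cross-correlates every kernel
#' with it (valid mode, stride 1), and clips responses strictly below the
#' bank's threshold to zero. With \code{padding = floor(window/2)} the
#' spatial size is preserved.
#'
#' @param image numeric matrix of intensities.
#' @param bank a [filter_bank()].
#' @return 3-D array (feature, row, col) of filter responses.
#' @export
apply_filter_bank <- function(image, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (!is.matrix(image)) stop("`image` must be a matrix")
  padded <- pad_matrix(image, bank$padding)
  maps <- lapply(bank$kernels, function(k) cross_correlate2d(padded, k))
  out <- array(0, dim = c(length(maps), nrow(maps[[1L]]), ncol(maps[[1L]])))
  for (f in seq_along(maps)) out[f, , ] <- maps[[f]]
  out[out < bank$clip_threshold] <- 0
  out
}

#' Local (regional-mean) normalization of an intensity map
#'
#' Divides each value by the mean of its square neighbourhood (truncated at
#' the borders), plus a small positive floor that keeps dark regions from
#' dividing by zero. This flattens global contrast so that latency coding
#' reflects local salience rather than absolute brightness.
#'
#' @param map 3-D intensity array (feature, row, col), non-negative.
#' @param region_size odd positive neighbourhood side length.
#' @param eps positive floor added to the regional mean.
#' @return array of the same shape; non-negative input gives non-negative
#'   output.
#' @export
local_normalization <- function(map, region_size, eps = 1e-12) {
  check_window(region_size)
  if (!is.array(map) || length(dim(map)) != 3L)
    stop("`map` must be a 3-D array (feature, row, col)")
  if (eps <= 0) stop("`eps` must be positive")
  half <- (region_size - 1L) %/% 2L
  d <- dim(map)
  out <- map
  box <- matrix(1, region_size, region_size)
  ones <- matrix(1, d[2L], d[3L])
  counts <- cross_correlate2d(pad_matrix(ones, half), box)
  for (f in seq_len(d[1L])) {
    plane <- matrix(map[f, , ], d[2L], d[3L])
    sums <- cross_correlate2d(pad_matrix(plane, half), box)
    out[f, , ] <- plane / (sums / counts + eps)
  }
  out
}

#' Lateral inhibition between nearby input intensities
#'
#' Sharpens the input representation before latency coding: scanning pixels
#' once in descending order of their original intensity, each salient pixel
#' that has not itself been suppressed multiplies its neighbours' intensities
#' by the kernel's survival factors (lower intensity means a later spike). A
#' pixel that has already been suppressed by a stronger neighbour loses the
#' right to suppress others. Feature maps are treated independently; no
#' intensity ever increases.
#'
#' @param map 3-D intensity array (feature, row, col).
#' @param inhibition_kernel odd square matrix of factors in \code{[0, 1]}
#'   (see [generate_inhibition_kernel()]).
#' @return array of the same shape, element-wise \code{<= map}.
#' @export
intensity_lateral_inhibition <- function(map, inhibition_kernel) {
  if (!is.array(map) || length(dim(map)) != 3L)
    stop("`map` must be a 3-D array (feature, row, col)")
  k <- inhibition_kernel
  if (!is.matrix(k) || nrow(k) != ncol(k) || nrow(k) %% 2 != 1)
    stop("`inhibition_kernel` must be an odd square matrix")
  if (any(k < 0 | k > 1))
    stop("inhibition factors must lie in [0, 1]")
  d <- dim(map)
  half <- (nrow(k) - 1L) %/% 2L
  centre <- half + 1L
  out <- map
  for (f in seq_len(d[1L])) {
    plane <- matrix(map[f, , ], d[2L], d[3L])
    cur <- plane
    # row-major scan index breaks intensity ties deterministically
    rm_idx <- as.vector(matrix(seq_len(d[2L] * d[3L]), d[2L], d[3L],
                               byrow = TRUE))
    ord <- order(-as.vector(plane), rm_idx)
    suppressed <- matrix(FALSE, d[2L], d[3L])
    for (lin in ord) {
      pos <- arrayInd(lin, dim(plane))
      r <- pos[1L]; c <- pos[2L]
      if (cur[r, c] <= 0 || suppressed[r, c]) next
      for (dr in -half:half) {
        rr <- r + dr
        if (rr < 1L || rr > d[2L]) next
        for (dc in -half:half) {
          if (dr == 0L && dc == 0L) next
          cc <- c + dc
          if (cc < 1L || cc > d[3L]) next
          fac <- k[centre + dr, centre + dc]
          if (fac < 1) {
            cur[rr, cc] <- cur[rr, cc] * fac
            suppressed[rr, cc] <- TRUE
          }
        }
      }
    }
    out[f, , ] <- cur
  }
  out
}

#' Rank-order intensity-to-latency coding
#'
#' Converts an intensity map into an accumulative spike-wave: all strictly
#' positive intensities are ranked in descending order and partitioned into
#' \code{t_max} near-equal bins; the neurons in bin \code{k} (0-based) emit
#' their single spike at time-step \code{k}, so stronger drive always spikes
#' at an earlier-or-equal step. Zero intensities never spike. When the
#' positive count is not divisible by \code{t_max}, the earliest bins take
#' one extra element; ties across a bin boundary are broken by a fixed
#' row-major scan over (feature, row, col).
#'
#' @param map 3-D non-negative intensity array (feature, row, col).
#' @param t_max positive integer number of time-steps.
#' @return spike-wave tensor of shape (t_max, F, H, W).
#' @export
intensity_to_latency <- function(map, t_max) {
  if (!is.array(map) || length(dim(map)) != 3L)
    stop("`map` must be a 3-D array (feature, row, col)")
  if (!is.numeric(t_max) || length(t_max) != 1L || t_max < 1)
    stop("`t_max` must be a positive integer")
  v <- as.vector(map)
  if (anyNA(v) || any(!is.finite(v)) || any(v < 0))
    stop("intensities must be finite and non-negative")
  t_max <- as.integer(t_max)
  d <- dim(map)
  ai <- arrayInd(seq_along(v), d)
  rm_idx <- (ai[, 1L] - 1L) * d[2L] * d[3L] +
    (ai[, 2L] - 1L) * d[3L] + (ai[, 3L] - 1L)
  ord <- order(-v, rm_idx)
  sel <- ord[v[ord] > 0]
  times <- rep(NA_integer_, length(v))
  n <- length(sel)
  if (n > 0L) {
    base <- n %/% t_max
    extra <- n %% t_max
    sizes <- rep(base, t_max) + c(rep(1L, extra), rep(0L, t_max - extra))
    times[sel] <- rep.int(seq_len(t_max) - 1L, sizes)
  }
  spike_times_to_wave(array(times, dim = d), t_max)
}
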