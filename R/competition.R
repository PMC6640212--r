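# first firing step (0-based) per neuron from thresholded potentials;
# NA where the neuron never reaches threshold
first_fire_step <- function(tp) {
  d <- dim(tp)
  t_max <- d[1L]
  m <- matrix(tp != 0, nrow = t_max)
  # per column, the earliest TRUE row: weight row t by (t_max + 1 - t) so
  # the column maximum encodes the first firing step without a scan
  w <- (t_max + 1L - seq_len(t_max)) * m
  best <- do.call(pmax, lapply(seq_len(t_max), function(t) w[t, ]))
  step <- as.integer(t_max - best)
  step[best == 0] <- NA_integer_
  array(step, dim = d[-1L])
}

#' Winners-take-all selection over thresholded potentials
#'
#' Iteratively selects up to \code{k} winning neurons from a thresholded
#' potentials tensor. Winners are chosen first by the earliest firing step
#' (the first time-step with a non-zero thresholded potential), then by the
#' largest final-step potential, then by the lowest (feature, row, col) in
#' lexicographic order so selection is fully deterministic. After each
#' selection the winner's whole feature map is suppressed (successive
#' winners represent distinct features) together with every neuron within
#' Chebyshev distance \code{inhibition_radius} of the winner's location in
#' all feature maps. Fewer than \code{k} winners are returned when the
#' candidates run out.
#'
#' @param tp thresholded potentials (T, F, H, W); zeros mean sub-threshold.
#' @param k positive integer number of winners.
#' @param inhibition_radius non-negative Chebyshev radius of the spatial
#'   suppression square.
#' @param suppress_feature if \code{TRUE} (default), a winner's whole
#'   feature map is ruled out for subsequent winners, so the k winners
#'   carry k distinct features; set \code{FALSE} to suppress only the
#'   spatial neighbourhood.
#' @return a data.frame with one row per winner and columns \code{feature},
#'   \code{row}, \code{col} (1-based array subscripts), \code{step}
#'   (0-based firing step) and \code{potential} (final-step potential),
#'   ordered by (step ascending, potential descending).
#' @export
get_k_winners <- function(tp, k = 1L, inhibition_radius = 0L,
                          suppress_feature = TRUE) {
  d <- dim(tp)
  if (is.null(d) || length(d) != 4L)
    stop("`tp` must be a 4-D array")
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("`k` must be a positive integer")
  if (inhibition_radius < 0)
    stop("`inhibition_radius` must be non-negative")
  t_max <- d[1L]
  step <- first_fire_step(tp)
  pot <- array(tp[t_max, , , ], dim = d[-1L])
  alive <- !is.na(step)
  winners <- data.frame(feature = integer(), row = integer(),
                        col = integer(), step = integer(),
                        potential = numeric())
  for (w in seq_len(k)) {
    if (!any(alive)) break
    cand <- which(alive)
    s <- step[cand]
    cand <- cand[s == min(s)]
    p <- pot[cand]
    cand <- cand[p == max(p)]
    # lexicographic (feature, row, col) tie-break
    sub <- arrayInd(cand, d[-1L])
    o <- order(sub[, 1L], sub[, 2L], sub[, 3L])
    pick <- cand[o[1L]]
    ps <- arrayInd(pick, d[-1L])
    winners <- rbind(winners, data.frame(
      feature = ps[1L], row = ps[2L], col = ps[3L],
      step = step[pick], potential = pot[pick]))
    if (suppress_feature) alive[ps[1L], , ] <- FALSE
    else alive[ps[1L], ps[2L], ps[3L]] <- FALSE
    if (inhibition_radius >= 0) {
      rr <- max(1L, ps[2L] - inhibition_radius):
        min(d[3L], ps[2L] + inhibition_radius)
      cc <- max(1L, ps[3L] - inhibition_radius):
        min(d[4L], ps[3L] + inhibition_radius)
      alive[, rr, cc] <- FALSE
    }
  }
  winners
}

#' Binary lateral-inhibition mask around winners
#'
#' Builds a (feature, row, col) mask that is 0 inside the square of
#' half-side \code{radius} (Chebyshev distance) around each winner's
#' location across every feature map, and 1 elsewhere; each winner's own
#' cell stays 1 so the winner itself survives.
#'
#' @param shape integer vector (F, H, W).
#' @param winners data.frame as returned by [get_k_winners()].
#' @param radius non-negative Chebyshev radius.
#' @return binary array of shape (F, H, W).
#' @export
lateral_inhibition_mask <- function(shape, winners, radius) {
  if (length(shape) != 3L) stop("`shape` must be (features, rows, cols)")
  if (radius < 0) stop("`radius` must be non-negative")
  mask <- array(1, dim = shape)
  for (i in seq_len(nrow(winners))) {
    r <- winners$row[i]; c <- winners$col[i]
    rr <- max(1L, r - radius):min(shape[2L], r + radius)
    cc <- max(1L, c - radius):min(shape[3L], c + radius)
    mask[, rr, cc] <- 0
  }
  for (i in seq_len(nrow(winners)))
    mask[winners$feature[i], winners$row[i], winners$col[i]] <- 1
  mask
}

#' Pointwise inhibition: one winning feature per location
#'
#' Competition among features at each spatial location: only the most
#' salient feature (earliest firing step, ties broken by the larger
#' final-step potential, then the lower feature index) keeps its spike
#' column; all other features at that location are silenced. Locations
#' where no feature fires stay silent.
#'
#' @param tp thresholded potentials (T, F, H, W).
#' @return a valid spike-wave tensor with at most one spiking feature per
#'   location.
#' @export
pointwise_inhibition <- function(tp) {
  d <- dim(tp)
  if (is.null(d) || length(d) != 4L)
    stop("`tp` must be a 4-D array")
  t_max <- d[1L]
  step <- first_fire_step(tp)
  pot <- array(tp[t_max, , , ], dim = d[-1L])
  times <- array(NA_integer_, dim = d[-1L])
  for (r in seq_len(d[3L])) {
    for (c in seq_len(d[4L])) {
      s <- step[, r, c]
      if (all(is.na(s))) next
      cand <- which(!is.na(s) & s == min(s, na.rm = TRUE))
      if (length(cand) > 1L) {
        p <- pot[cand, r, c]
        cand <- cand[p == max(p)]
      }
      f <- cand[1L]
      times[f, r, c] <- step[f, r, c]
    }
  }
  spike_times_to_wave(times, t_max)
}

#' Silence whole feature maps
#'
#' Zeroes the listed feature maps at every time-step, leaving the others
#' untouched; with randomly chosen features this implements dropout for
#' spike-wave tensors.
#'
#' @param wave spike-wave tensor (T, F, H, W).
#' @param features integer vector of feature indices (1-based) to inhibit;
#'   may be empty.
#' @return spike-wave tensor of the same shape.
#' @export
feature_inhibition <- function(wave, features) {
  d <- dim(wave)
  if (is.null(d) || length(d) != 4L)
    stop("`wave` must be a 4-D array")
  if (length(features) == 0L) return(wave)
  features <- as.integer(features)
  if (any(features < 1L | features > d[2L]))
    stop("feature index out of range")
  wave[, features, , ] <- 0
  wave
}
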