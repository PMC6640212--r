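#' Generate a synthetic class-structured image set
#'
#' Produces a labeled set of grayscale images for desk-scale experiments:
#' each class is a distinct oriented bar through the image centre (class k
#' at orientation k * pi / n_classes), rendered with a soft profile, then
#' jittered by up to one pixel in each direction and corrupted with
#' additive Gaussian noise. Intensities are clipped to [0, 1]. The set is
#' deterministic per seed: the same seed yields a bit-identical dataset,
#' and the caller's random-number state is left untouched.
#'
#' @param n_classes number of classes (>= 2).
#' @param samples_per_class images per class.
#' @param image_size side length of the square images (>= 9, so the
#'   three-stage kernel geometry produces spikes everywhere).
#' @param noise_level standard deviation of the additive pixel noise.
#' @param seed integer seed governing jitter and noise.
#' @return an unlabeled-transform [sw_dataset()] of image matrices with
#'   integer labels \code{0 .. n_classes - 1}.
#' @export
generate_synthetic_dataset <- function(n_classes = 2L,
                                       samples_per_class = 30L,
                                       image_size = 24L,
                                       noise_level = 0.05,
                                       seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be at least 2")
  if (samples_per_class < 1L) stop("`samples_per_class` must be positive")
  if (image_size < 9L) stop("`image_size` must be at least 9")
  if (noise_level < 0) stop("`noise_level` must be non-negative")
  with_preserved_rng({
    set.seed(as.integer(seed))
    items <- list()
    labels <- integer(0)
    for (k in seq_len(n_classes) - 1L) {
      proto_theta <- k * pi / n_classes
      for (s in seq_len(samples_per_class)) {
        jitter <- sample(-1:1, 2L, replace = TRUE)
        img <- render_bar(image_size, proto_theta,
                          offset = jitter)
        if (noise_level > 0)
          img <- img + matrix(stats::rnorm(image_size^2, 0, noise_level),
                              image_size, image_size)
        img <- pmin(pmax(img, 0), 1)
        items[[length(items) + 1L]] <- img
        labels <- c(labels, k)
      }
    }
    # interleave classes so training never sees long single-class runs
    ord <- order(rep(seq_len(samples_per_class), n_classes))
    sw_dataset(items[ord], labels[ord])
  })
}

# soft-edged bar of the given orientation through the (offset) centre
render_bar <- function(size, theta, offset = c(0L, 0L),
                       thickness = 2.5, length_frac = 0.75) {
  cx <- (size + 1) / 2 + offset[1L]
  cy <- (size + 1) / 2 + offset[2L]
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  y <- matrix(seq_len(size), size, size) - cy
  along <- x * cos(theta) + y * sin(theta)
  perp <- -x * sin(theta) + y * cos(theta)
  half_len <- size * length_frac / 2
  prof <- pmax(0, 1 - (perp / thickness)^2)
  prof[abs(along) > half_len] <- 0
  prof
}

# evaluate `expr` with the global RNG state saved and restored
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
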