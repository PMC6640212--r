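#' Difference-of-Gaussians (DoG) kernel
#'
#' Builds a centre--surround contrast detector: the difference of two
#' unit-mass 2-D Gaussians evaluated on an odd square window, with the mean
#' removed so a uniform region produces zero response. With
#' \code{sigma_center < sigma_surround} the kernel is ON-centre (bright spot
#' on dark background excites); swapping the widths negates the kernel
#' (OFF-centre).
#'
#' @param window_size odd positive integer side length of the kernel.
#' @param sigma_center,sigma_surround positive standard deviations (pixels)
#'   of the centre and surround Gaussians; must differ.
#' @return a \code{window_size x window_size} numeric matrix summing to ~0.
#' @export
make_dog_kernel <- function(window_size, sigma_center, sigma_surround) {
  check_window(window_size)
  if (sigma_center <= 0 || sigma_surround <= 0)
    stop("Gaussian widths must be positive")
  if (sigma_center == sigma_surround)
    stop("`sigma_center` and `sigma_surround` must differ")
  half <- (window_size - 1L) / 2
  g <- function(sigma) {
    d <- stats::dnorm(seq(-half, half), sd = sigma)
    outer(d, d)
  }
  k <- g(sigma_center) - g(sigma_surround)
  k - mean(k)
}

#' Even-symmetric Gabor kernel
#'
#' An oriented edge/bar detector: a cosine grating of the given wavelength
#' and orientation under a Gaussian envelope, evaluated on an odd square
#' window and mean-subtracted. Even symmetry (cosine phase) makes the kernel
#' identical under a half-turn of the orientation.
#'
#' @param window_size odd positive integer side length.
#' @param wavelength wavelength of the grating in pixels (> 0).
#' @param orientation grating orientation in radians (0 = horizontal grating
#'   varying along x).
#' @param width standard deviation of the Gaussian envelope in pixels.
#' @param aspect spatial aspect ratio of the envelope (1 = isotropic).
#' @return a \code{window_size x window_size} numeric matrix summing to ~0.
#' @export
make_gabor_kernel <- function(window_size, wavelength, orientation,
                              width = window_size / 5, aspect = 0.5) {
  check_window(window_size)
  if (wavelength <= 0) stop("`wavelength` must be positive")
  if (width <= 0) stop("`width` must be positive")
  half <- (window_size - 1L) / 2
  x <- matrix(seq(-half, half), window_size, window_size, byrow = TRUE)
  y <- matrix(seq(half, -half), window_size, window_size)
  xr <- x * cos(orientation) + y * sin(orientation)
  yr <- -x * sin(orientation) + y * cos(orientation)
  k <- exp(-(xr^2 + (aspect * yr)^2) / (2 * width^2)) *
    cos(2 * pi * xr / wavelength)
  k - mean(k)
}

#' Lateral-inhibition kernel from a series of inhibition factors
#'
#' Builds the square multiplicative kernel used by
#' [intensity_lateral_inhibition()]: the centre is 1 (a salient point never
#' suppresses itself) and every cell at Chebyshev distance \code{d} from the
#' centre carries \code{factors[d]}, a multiplicative survival factor in
#' \code{[0, 1]} (0 = total suppression, 1 = no effect).
#'
#' @param factors non-empty numeric vector of factors in \code{[0, 1]},
#'   ordered by increasing distance ring.
#' @return a \code{(2 * length(factors) + 1)} square matrix.
#' @examples
#' generate_inhibition_kernel(c(0.5, 0.9))
#' @export
generate_inhibition_kernel <- function(factors) {
  if (length(factors) == 0L) stop("`factors` must be non-empty")
  if (any(factors < 0 | factors > 1))
    stop("inhibition factors must lie in [0, 1]")
  n <- length(factors)
  side <- 2L * n + 1L
  centre <- n + 1L
  idx <- seq_len(side)
  cheb <- pmax(abs(outer(idx, idx, function(i, j) i - centre)),
               abs(outer(idx, idx, function(i, j) j - centre)))
  k <- matrix(1, side, side)
  k[cheb > 0] <- factors[cheb[cheb > 0]]
  k
}

check_window <- function(window_size) {
  if (!is.numeric(window_size) || length(window_size) != 1L ||
      window_size < 1 || window_size %% 2 != 1)
    stop("`window_size` must be an odd positive integer")
  invisible(TRUE)
}
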