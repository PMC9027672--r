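#' Gabor filter parameters
#'
#' A Gabor kernel is a sinusoidal carrier under a Gaussian envelope — a
#' localized bandpass filter selective for one spatial frequency and
#' orientation, which makes a small bank of them a standard
#' texture-enhancement/denoising front end for grayscale images.
#'
#' @param wavelength Pixels per sinusoid cycle (> 0).
#' @param orientation Carrier orientation in radians.
#' @param sigma Gaussian envelope standard deviation in pixels (> 0);
#'   defaults to `wavelength / 2`.
#' @param aspect_ratio Envelope ellipticity (default 0.5).
#' @param phase Carrier phase in radians (default 0, even/cosine kernel).
#' @param kernel_size Odd kernel side length >= 3; defaults to
#'   `2 * ceiling(3 * sigma) + 1`.
#' @return A `gabor_params` list.
#' @export
gabor_params <- function(wavelength, orientation = 0, sigma = wavelength / 2,
                         aspect_ratio = 0.5, phase = 0, kernel_size = NULL) {
  if (wavelength <= 0) stop("`wavelength` must be positive", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (aspect_ratio <= 0) stop("`aspect_ratio` must be positive", call. = FALSE)
  if (is.null(kernel_size)) kernel_size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be an odd integer >= 3", call. = FALSE)
  }
  structure(list(wavelength = wavelength, orientation = orientation,
                 sigma = sigma, aspect_ratio = aspect_ratio, phase = phase,
                 kernel_size = kernel_size),
            class = "gabor_params")
}

#' Real Gabor kernel
#'
#' Evaluates
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * cos(2 pi x' / lambda + psi)`
#' on a centered `kernel_size x kernel_size` grid, where `(x', y')` are the
#' coordinates rotated by the orientation. The center entry equals
#' `cos(phase)` (unit envelope at the origin).
#'
#' @param params A [gabor_params()].
#' @return Numeric `kernel_size x kernel_size` matrix.
#' @export
gabor_kernel <- function(params) {
  if (!inherits(params, "gabor_params")) stop("expected gabor_params()", call. = FALSE)
  half <- (params$kernel_size - 1L) %/% 2L
  g <- seq(-half, half)
  x <- matrix(g, params$kernel_size, params$kernel_size, byrow = TRUE)
  y <- matrix(g, params$kernel_size, params$kernel_size)
  th <- params$orientation
  xp <- x * cos(th) + y * sin(th)
  yp <- -x * sin(th) + y * cos(th)
  env <- exp(-(xp^2 + params$aspect_ratio^2 * yp^2) / (2 * params$sigma^2))
  env * cos(2 * pi * xp / params$wavelength + params$phase)
}

#' Default Gabor bank
#'
#' Four orientations `{0, pi/4, pi/2, 3*pi/4}` at a single wavelength —
#' a standard texture bank covering the principal directions.
#'
#' @param wavelength Pixels per cycle (default 8).
#' @param sigma Envelope sd (default `wavelength / 2`).
#' @return List of [gabor_params()].
#' @export
default_gabor_bank <- function(wavelength = 8, sigma = wavelength / 2) {
  lapply(c(0, pi / 4, pi / 2, 3 * pi / 4), function(o) {
    gabor_params(wavelength = wavelength, orientation = o, sigma = sigma)
  })
}

# Reflect-pad a matrix by `k` pixels on every side.
.reflect_pad <- function(mat, k) {
  n <- nrow(mat)
  m <- ncol(mat)
  ri <- c(rev(seq_len(k) + 1L), seq_len(n), n - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(m), m - seq_len(k))
  mat[ri, ci, drop = FALSE]
}

#' Raw linear response of one Gabor kernel
#'
#' Convolves the image with the kernel under reflect padding, without any
#' rescaling or quantization; the map is linear in the input. An impulse
#' image reproduces the kernel around the impulse location.
#'
#' @param image A [gray_image()] or numeric matrix.
#' @param params A [gabor_params()].
#' @return Numeric matrix of the same shape as `image`.
#' @export
gabor_response <- function(image, params) {
  k <- gabor_kernel(params)
  half <- (params$kernel_size - 1L) %/% 2L
  mat <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (half >= nrow(mat) || half >= ncol(mat)) {
    stop("kernel is too large for this image", call. = FALSE)
  }
  padded <- .reflect_pad(mat, half)
  resp <- EBImage::filter2(padded, k, boundary = "circular")
  resp[(half + 1L):(half + nrow(mat)), (half + 1L):(half + ncol(mat))]
}

#' Gabor-bank filtering of an image
#'
#' Applies every kernel of the bank ([gabor_response()]), combines the
#' responses (`"max"`: elementwise maximum of response magnitudes, the
#' default; `"mean"`: elementwise mean of raw responses), and re-quantizes
#' the combined map to integers in `[0, L - 1]` by min-max rescaling so the
#' output is again a well-defined gray-level image. A constant combined map
#' (e.g. from an all-zero input) maps to all zeros.
#'
#' @param image A [gray_image()].
#' @param bank Non-empty list of [gabor_params()]
#'   (default [default_gabor_bank()]).
#' @param combine `"max"` or `"mean"`.
#' @return A [gray_image()] with the same dimensions and level count.
#' @export
gabor_filter <- function(image, bank = default_gabor_bank(),
                         combine = c("max", "mean")) {
  assert_gray_image(image)
  combine <- match.arg(combine)
  if (length(bank) < 1L) stop("`bank` must contain at least one kernel", call. = FALSE)
  L <- gray_levels(image)
  responses <- lapply(bank, function(p) gabor_response(image, p))
  combined <- if (combine == "max") {
    Reduce(pmax, lapply(responses, abs))
  } else {
    Reduce(`+`, responses) / length(responses)
  }
  rng <- range(combined)
  out <- if (rng[2] > rng[1]) {
    round((combined - rng[1]) / (rng[2] - rng[1]) * (L - 1L))
  } else {
    matrix(0, nrow(combined), ncol(combined))
  }
  gray_image(matrix(as.integer(out), nrow(out), ncol(out)), L = L)
}
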