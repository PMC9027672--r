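#' Grayscale image container
#'
#' A `gray_image` is an integer pixel matrix together with its gray-level
#' count `L`. Pixel values are integers in `[0, L - 1]`, stored row/column
#' as a base R matrix (`height` rows, `width` columns).
#'
#' @param pixels Numeric matrix of integer-valued intensities.
#' @param L Number of gray levels (default 256); valid intensities are
#'   `0 ... L - 1`.
#' @return An object of class `gray_image`: the pixel matrix with an `L`
#'   attribute.
#' @examples
#' img <- gray_image(matrix(0:63, 8, 8), L = 64)
#' dim(img)
#' @export
gray_image <- function(pixels, L = 256L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8x8 pixels", call. = FALSE)
  }
  L <- as.integer(L)
  if (is.na(L) || L < 2L) stop("`L` must be an integer >= 2", call. = FALSE)
  if (anyNA(pixels)) stop("`pixels` contains missing values", call. = FALSE)
  if (any(pixels != round(pixels))) {
    stop("`pixels` must be integer-valued", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > L - 1L) {
    stop("pixel values must lie in [0, L-1]", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, L = L, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, L = %d, range [%d, %d]>\n",
              nrow(x), ncol(x), gray_levels(x), min(x), max(x)))
  invisible(x)
}

#' Number of gray levels of an image
#' @param image A [gray_image()].
#' @return Integer `L`.
#' @export
gray_levels <- function(image) {
  L <- attr(image, "L")
  if (is.null(L)) 256L else as.integer(L)
}

is_gray_image <- function(x) inherits(x, "gray_image")

assert_gray_image <- function(x, arg = "image") {
  if (!is_gray_image(x)) {
    stop(sprintf("`%s` must be a gray_image (see gray_image())", arg),
         call. = FALSE)
  }
  invisible(x)
}

#' Read and write 8-bit grayscale PNG images
#'
#' Thin wrappers around the png package mapping between `gray_image`
#' (integer levels in `[0, 255]`) and normalised PNG intensities.
#'
#' @param image A [gray_image()] with `L <= 256`.
#' @param path File path.
#' @return `write_image_png()` returns `path` invisibly; `read_image_png()`
#'   returns a [gray_image()] with `L = 256`.
#' @export
write_image_png <- function(image, path) {
  assert_gray_image(image)
  L <- gray_levels(image)
  if (L > 256L) stop("PNG export supports at most 256 gray levels", call. = FALSE)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  gray_image(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)),
             L = 256L)
}
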