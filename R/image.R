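#' Grayscale image container
#'
#' Images throughout the package are plain integer matrices with intensities
#' in `[0, L-1]` (rows = image rows, top to bottom; columns = image columns,
#' left to right). `gray_image()` validates and coerces a matrix into that
#' contract; most functions accept any matrix that satisfies it.
#'
#' @param pixels numeric matrix of intensities.
#' @param L number of gray levels (bit depth); default 256 (8-bit).
#' @return an integer matrix with attribute `L`.
#' @export
gray_image <- function(pixels, L = 256L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be at least 1x1")
  if (anyNA(pixels)) stop("image contains missing values")
  p <- round(pixels)
  if (any(p < 0) || any(p > L - 1)) {
    stop(sprintf("pixel values outside [0, %d]", L - 1L))
  }
  storage.mode(p) <- "integer"
  attr(p, "L") <- as.integer(L)
  p
}

#' @rdname gray_image
#' @param img object to test.
#' @export
is_gray_image <- function(img, L = 256L) {
  is.matrix(img) && !anyNA(img) && all(img >= 0) && all(img <= L - 1) &&
    all(img == round(img))
}

# Clip to [0, L-1] and round to integer; used after every filtering stage.
clip_quantize <- function(x, L = 256L) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > L - 1] <- L - 1L
  storage.mode(x) <- "integer"
  x
}

#' Read / write 8-bit grayscale PNG images
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()]. Color or alpha
#' channels are collapsed to luminance on read (equal-weight mean), and values
#' are rescaled from `[0, 1]` to integer `[0, 255]`.
#'
#' @param path file path.
#' @return `read_gray_png`: an integer matrix in `[0, 255]`.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3L, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  gray_image(round(a * 255))
}

#' @rdname read_gray_png
#' @param img integer matrix in `[0, 255]`.
#' @export
write_gray_png <- function(img, path) {
  stopifnot(is_gray_image(img))
  png::writePNG(img / 255, target = path)
  invisible(path)
}
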