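#' Extract a fixed-size region of interest
#'
#' Crops a `size` x `size` window centered on a lesion. For even `size` the
#' window is asymmetric by one pixel: with a 1-based center `(r, c)` it spans
#' rows `r - size/2` through `r + size/2 - 1` (likewise columns), i.e. the
#' center pixel sits at index `size/2 + 1` within the patch. A window that
#' does not lie fully inside the image is an error — there is no silent
#' clamping, because a shifted window would no longer be lesion-centered.
#'
#' @param img integer image matrix.
#' @param center length-2 vector `(row, col)`, 1-based.
#' @param size window side length in pixels (default 40).
#' @return the cropped `size` x `size` integer matrix.
#' @export
extract_roi <- function(img, center, size = 40L) {
  stopifnot(is.matrix(img), length(center) == 2L, size >= 1L)
  r <- as.integer(center[1]); c <- as.integer(center[2])
  half <- size %/% 2L
  r0 <- r - half; r1 <- r0 + size - 1L
  c0 <- c - half; c1 <- c0 + size - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(img) || c1 > ncol(img)) {
    stop(sprintf(
      "ROI window rows %d..%d, cols %d..%d falls outside the %dx%d image",
      r0, r1, c0, c1, nrow(img), ncol(img)))
  }
  img[r0:r1, c0:c1, drop = FALSE]
}

#' Paste a patch back at a center (inverse of [extract_roi()])
#'
#' @inheritParams extract_roi
#' @param patch square patch previously extracted at `center`.
#' @return the image with the window replaced by `patch`.
#' @export
embed_roi <- function(img, patch, center) {
  stopifnot(is.matrix(patch), nrow(patch) == ncol(patch))
  size <- nrow(patch)
  half <- size %/% 2L
  r0 <- as.integer(center[1]) - half
  c0 <- as.integer(center[2]) - half
  img[r0:(r0 + size - 1L), c0:(c0 + size - 1L)] <- patch
  img
}

#' Regional maxima of a grayscale image
#'
#' Marks every connected plateau (8-connectivity) whose value is strictly
#' greater than all pixels adjacent to the plateau — the classic
#' morphological regional-maxima operator used to highlight bright lesion
#' cores. A constant image is a single plateau with no external neighbors and
#' is marked everywhere. This is a visualization / QA aid; it is not on the
#' feature-extraction path.
#'
#' @param img integer image matrix.
#' @return logical matrix of the same shape, `TRUE` on regional maxima.
#' @export
regional_maxima <- function(img) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  n <- h * w
  visited <- logical(n)
  mask <- logical(n)
  val <- as.vector(img)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in seq_len(n)) {
    if (visited[start]) next
    # flood the equal-value plateau containing `start`
    v <- val[start]
    queue <- start
    visited[start] <- TRUE
    comp <- integer(0)
    is_max <- TRUE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      comp <- c(comp, p)
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      nr <- pr + offs$dr
      nc <- pc + offs$dc
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nb <- (nc[ok] - 1L) * h + nr[ok]
      higher <- val[nb] > v
      if (any(higher)) is_max <- FALSE
      same <- nb[val[nb] == v & !visited[nb]]
      if (length(same)) {
        visited[same] <- TRUE
        queue <- c(queue, same)
      }
    }
    if (is_max) mask[comp] <- TRUE
  }
  matrix(mask, h, w)
}
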