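#' Gray-level run-length matrix
#'
#' Scans every maximal line of pixels along a direction (rows for 0 degrees,
#' columns for 90, the two diagonal families for 45 and 135) and counts each
#' maximal constant-intensity run once: `R[i, l]` is the number of runs of
#' quantized level `i` (1-based level index = quantized value + 1) with
#' length `l`. Every pixel belongs to exactly one maximal run, so
#' `sum(l * R[, l]) == Np` — the pixel-conservation invariant checked in the
#' test suite against a brute-force scanner.
#'
#' @param patch integer matrix; raw intensities unless `quantized = TRUE`.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @param G number of quantized gray levels.
#' @param quantized is `patch` already in `0 .. G-1`?
#' @param L input bit depth when quantizing.
#' @return an object of class `"glrlm"`: list with `R` (G x Rmax integer
#'   matrix), `Np` (pixel count), `Nr` (run count) and `direction`.
#' @export
compute_glrlm <- function(patch, direction = 0, G = 8L, quantized = FALSE,
                          L = 256L) {
  stopifnot(is.matrix(patch))
  q <- if (quantized) patch else quantize(patch, G, L)
  if (any(q < 0) || any(q > G - 1L)) stop("quantized values outside 0..G-1")
  h <- nrow(q); w <- ncol(q)
  lines <- switch(as.character(direction),
    "0"   = lapply(seq_len(h), function(r) q[r, ]),
    "90"  = lapply(seq_len(w), function(c) q[, c]),
    # 45 degrees: direction (-1, +1) -> anti-diagonals (r + c constant)
    "45"  = {
      s <- row(q) + col(q)
      lapply(split(q[order(s, -row(q))], sort(as.vector(s))), as.vector)
    },
    # 135 degrees: direction (-1, -1) -> main diagonals (r - c constant)
    "135" = {
      s <- row(q) - col(q)
      lapply(split(q[order(s, -row(q))], sort(as.vector(s))), as.vector)
    },
    stop("direction must be one of 0, 45, 90, 135"))
  rmax <- max(lengths(lines))
  R <- matrix(0L, G, rmax)
  for (ln in lines) {
    r <- rle(as.vector(ln))
    for (k in seq_along(r$lengths)) {
      i <- r$values[k] + 1L
      l <- r$lengths[k]
      R[i, l] <- R[i, l] + 1L
    }
  }
  structure(list(R = R, Np = h * w, Nr = sum(R),
                 direction = direction, G = as.integer(G)),
            class = "glrlm")
}

#' Names of the 7 run-length features, in output order
#' @export
GLRLM_FEATURES <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE")

# seven Galloway / Chu run-emphasis features from one run-length matrix;
# 1-based level and length indices in the emphasis weights (the universal
# convention -- 0-based levels would divide by zero in LGRE)
glrlm_features_one <- function(rl) {
  R <- rl$R
  Nr <- rl$Nr; Np <- rl$Np
  i <- seq_len(nrow(R))       # gray-level index, 1-based
  l <- seq_len(ncol(R))       # run length
  ri <- rowSums(R)            # runs per gray level
  rl_ <- colSums(R)           # runs per length
  c(
    SRE  = sum(t(R) / l^2) / Nr,
    LRE  = sum(t(R) * l^2) / Nr,
    GLN  = sum(ri^2) / Nr,
    RLN  = sum(rl_^2) / Nr,
    RP   = Nr / Np,
    LGRE = sum(R / i^2) / Nr,
    HGRE = sum(R * i^2) / Nr
  )
}

#' The 7-feature run-length vector of a patch
#'
#' Short/Long Run Emphasis, Gray-Level and Run-Length Non-uniformity, Run
#' Percentage, and Low/High Gray-Level Run Emphasis, averaged over the four
#' scan directions (matching the co-occurrence module's angle averaging) and
#' returned in the fixed order [GLRLM_FEATURES]. Formulas are the classic
#' run-length definitions with 1-based level and length indices.
#'
#' @inheritParams compute_glrlm
#' @param directions directions to average over.
#' @return named numeric vector of length 7.
#' @export
glrlm_feature_vector <- function(patch, G = 8L,
                                 directions = c(0, 45, 90, 135),
                                 quantized = FALSE, L = 256L) {
  stopifnot(is.matrix(patch), length(patch) >= 1L)
  per <- vapply(directions, function(dd) {
    glrlm_features_one(compute_glrlm(patch, dd, G = G,
                                     quantized = quantized, L = L))
  }, numeric(length(GLRLM_FEATURES)))
  out <- rowMeans(per)
  names(out) <- GLRLM_FEATURES
  out
}
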