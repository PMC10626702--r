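#' Uniform gray-level quantization
#'
#' Bins 8-bit intensities into `G` levels: `q = floor(pixel * G / L)`,
#' clipped to `G - 1`. Shared by the co-occurrence and run-length extractors
#' so their features are computed on identical level sets.
#'
#' @param patch integer matrix in `[0, L-1]`.
#' @param G number of quantized levels (>= 2).
#' @param L input bit depth (default 256).
#' @return integer matrix with values in `0 .. G-1`.
#' @export
quantize <- function(patch, G = 8L, L = 256L) {
  stopifnot(is.matrix(patch), G >= 2L)
  q <- pmin(floor(patch * (G / L)), G - 1L)
  storage.mode(q) <- "integer"
  q
}

# displacement (drow, dcol) for an angle in degrees, distance d;
# row index increases downward
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Builds the normalized co-occurrence matrix `P(i, j | d, theta)`: the joint
#' frequency of quantized gray-level pairs `(i, j)` at displacement `d`
#' along each requested angle. With `symmetric = TRUE` each pixel pair is
#' counted in both orderings, making `P` symmetric. Counts from all requested
#' angles are pooled into one matrix before normalization (use a single angle
#' to get per-angle matrices; [glcm_feature_vector()] averages features over
#' per-angle matrices).
#'
#' The returned object carries the marginal statistics used by the feature
#' formulas: `px`, `py` (row/column marginals of `P`), their index-weighted
#' means `mux`, `muy` and standard deviations `sdx`, `sdy`. Indices `i, j`
#' run `0 .. G-1` in all moment computations.
#'
#' @param patch integer matrix; raw `[0, L-1]` intensities unless
#'   `quantized = TRUE`, in which case values must already lie in `0 .. G-1`.
#' @param d displacement distance in pixels (>= 1).
#' @param angles subset of `c(0, 45, 90, 135)` degrees.
#' @param G number of gray levels in the matrix.
#' @param symmetric count both pair orderings (default TRUE).
#' @param quantized is `patch` already quantized?
#' @param L input bit depth when quantizing.
#' @return an object of class `"glcm"`.
#' @export
compute_glcm <- function(patch, d = 1L, angles = c(0, 45, 90, 135), G = 8L,
                         symmetric = TRUE, quantized = FALSE, L = 256L) {
  stopifnot(is.matrix(patch), d >= 1L, length(angles) >= 1L)
  q <- if (quantized) patch else quantize(patch, G, L)
  if (any(q < 0) || any(q > G - 1L)) stop("quantized values outside 0..G-1")
  h <- nrow(q); w <- ncol(q)
  counts <- matrix(0, G, G)
  npairs <- 0L
  for (a in angles) {
    off <- glcm_offset(a, as.integer(d))
    rs <- seq_len(h)[(seq_len(h) + off[1]) >= 1L & (seq_len(h) + off[1]) <= h]
    cs <- seq_len(w)[(seq_len(w) + off[2]) >= 1L & (seq_len(w) + off[2]) <= w]
    if (!length(rs) || !length(cs)) next
    from <- q[rs, cs, drop = FALSE]
    to <- q[rs + off[1], cs + off[2], drop = FALSE]
    tab <- table(factor(from, levels = 0:(G - 1L)),
                 factor(to, levels = 0:(G - 1L)))
    counts <- counts + unclass(tab)
    npairs <- npairs + length(from)
  }
  if (npairs == 0L) {
    stop(sprintf("no valid pixel pairs at distance %d for a %dx%d patch", d, h, w))
  }
  if (symmetric) counts <- counts + t(counts)
  dimnames(counts) <- NULL
  P <- counts / sum(counts)
  i0 <- 0:(G - 1L)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i0 * px); muy <- sum(i0 * py)
  structure(list(
    P = P, G = as.integer(G), d = as.integer(d), angles = angles,
    symmetric = symmetric,
    px = px, py = py, mux = mux, muy = muy,
    sdx = sqrt(sum((i0 - mux)^2 * px)),
    sdy = sqrt(sum((i0 - muy)^2 * py))
  ), class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: G=%d, d=%d, angles={%s}, %s\n", x$G, x$d,
              paste(x$angles, collapse = ","),
              if (x$symmetric) "symmetric" else "asymmetric"))
  print(round(x$P, 4))
  invisible(x)
}

#' Scalar texture statistics of a co-occurrence matrix
#'
#' The four statistics with printed reference formulas:
#' * energy `sum(P^2)` — 1 for a constant image;
#' * contrast `sum_n n^2 sum_{|i-j|=n} P(i,j)` (equivalently
#'   `sum (i-j)^2 P`);
#' * correlation `(sum ij P - mux*muy) / (sdx*sdy)`, in `[-1, 1]`;
#' * homogeneity `sum P / (1 + |i-j|)` — 1 iff all mass is diagonal.
#'
#' A constant patch has zero marginal spread; its correlation is defined as 0
#' with a warning rather than NaN so batch pipelines never crash on flat
#' regions of interest.
#'
#' @param glcm object from [compute_glcm()].
#' @return a single numeric value.
#' @export
glcm_energy <- function(glcm) sum(glcm$P^2)

#' @rdname glcm_energy
#' @export
glcm_contrast <- function(glcm) {
  i0 <- 0:(glcm$G - 1L)
  D <- outer(i0, i0, "-")
  sum(D^2 * glcm$P)
}

#' @rdname glcm_energy
#' @export
glcm_correlation <- function(glcm) {
  if (glcm$sdx == 0 || glcm$sdy == 0) {
    warning("degenerate GLCM (zero marginal sd): correlation defined as 0")
    return(0)
  }
  i0 <- 0:(glcm$G - 1L)
  (sum(outer(i0, i0) * glcm$P) - glcm$mux * glcm$muy) / (glcm$sdx * glcm$sdy)
}

#' @rdname glcm_energy
#' @export
glcm_homogeneity <- function(glcm) {
  i0 <- 0:(glcm$G - 1L)
  sum(glcm$P / (1 + abs(outer(i0, i0, "-"))))
}

#' Names of the 13 co-occurrence features, in output order
#' @export
GLCM_FEATURES <- c(
  "autocorrelation", "contrast", "correlation", "cluster_prominence",
  "cluster_shade", "energy", "dissimilarity", "homogeneity",
  "info_measure_corr1", "maximum_probability", "inverse_difference",
  "inverse_difference_normalized", "inverse_difference_moment_normalized")

# all 13 features from a single glcm object, 0-based indices throughout.
# Natural log is used in the entropies of the information measure (numerator
# and denominator share the base, so the ratio is base-invariant).
glcm_features_one <- function(g) {
  P <- g$P
  i0 <- 0:(g$G - 1L)
  I <- outer(i0, i0, function(i, j) i)
  J <- t(I)
  Dabs <- abs(I - J)
  mu_sum <- g$mux + g$muy
  plogp <- function(p) ifelse(p > 0, p * log(p), 0)
  hx <- -sum(plogp(g$px)); hy <- -sum(plogp(g$py))
  hxy <- -sum(plogp(P))
  pipj <- outer(g$px, g$py)
  hxy1 <- -sum(ifelse(pipj > 0, P * log(pipj), 0))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  corr <- if (g$sdx == 0 || g$sdy == 0) 0 else
    (sum(I * J * P) - g$mux * g$muy) / (g$sdx * g$sdy)
  c(
    autocorrelation = sum(I * J * P),
    contrast = sum((I - J)^2 * P),
    correlation = corr,
    cluster_prominence = sum((I + J - mu_sum)^4 * P),
    cluster_shade = sum((I + J - mu_sum)^3 * P),
    energy = sum(P^2),
    dissimilarity = sum(Dabs * P),
    homogeneity = sum(P / (1 + Dabs)),
    info_measure_corr1 = imc1,
    maximum_probability = max(P),
    inverse_difference = sum(P / (1 + (I - J)^2)),
    inverse_difference_normalized = sum(P / (1 + Dabs / g$G)),
    inverse_difference_moment_normalized = sum(P / (1 + (I - J)^2 / g$G^2))
  )
}

#' The 13-feature co-occurrence vector of a patch
#'
#' Computes one co-occurrence matrix per requested angle and returns the
#' feature values averaged over angles (standard Haralick practice; it also
#' matches the fixed count of 13 features). See [GLCM_FEATURES] for the
#' names and order. `homogeneity` uses the `1/(1+|i-j|)` kernel of the
#' reference formula; `inverse_difference` uses the squared-difference kernel
#' `1/(1+(i-j)^2)` (the inverse-difference-moment convention) so the two
#' features are distinct; the normalized variants divide `|i-j|` by `G` and
#' `(i-j)^2` by `G^2`.
#'
#' @inheritParams compute_glcm
#' @return named numeric vector of length 13.
#' @export
glcm_feature_vector <- function(patch, d = 1L, angles = c(0, 45, 90, 135),
                                G = 8L, symmetric = TRUE, quantized = FALSE,
                                L = 256L) {
  per <- vapply(angles, function(a) {
    glcm_features_one(compute_glcm(patch, d = d, angles = a, G = G,
                                   symmetric = symmetric,
                                   quantized = quantized, L = L))
  }, numeric(length(GLCM_FEATURES)))
  out <- rowMeans(per)
  names(out) <- GLCM_FEATURES
  out
}
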