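#' Orthonormal Haar analysis filter pair
#'
#' Low-pass `h = (1, 1)/sqrt(2)` and high-pass `g = (1, -1)/sqrt(2)`. The
#' pair is orthonormal, so the filter-bank transform conserves energy
#' (Parseval) and is inverted exactly by its transpose.
#'
#' @return list with components `h` (low-pass) and `g` (high-pass).
#' @export
haar_filters <- function() list(h = c(1, 1) / sqrt(2), g = c(1, -1) / sqrt(2))

# 1-D analysis along the first dimension: y[k,] = sum_m f[m] x[(2(k-1)+m-1) mod n + 1, ]
# periodic boundary extension
filter_down <- function(x, f) {
  n <- nrow(x)
  half <- n %/% 2L
  y <- matrix(0, half, ncol(x))
  base <- 2L * (seq_len(half) - 1L)
  for (m in seq_along(f)) {
    y <- y + f[m] * x[((base + m - 1L) %% n) + 1L, , drop = FALSE]
  }
  y
}

#' Single-level separable 2-D wavelet analysis
#'
#' Rows of `A` are filtered with the low- and high-pass filters and
#' downsampled by two, then the columns of each result are filtered and
#' downsampled, yielding the four quarter-size subbands: approximation `LL`
#' and the details `LH` (high-pass along columns of the row-low-passed
#' image), `HL` (low-pass along columns of the row-high-passed image) and
#' `HH`. Boundary extension is periodic. With the default Haar pair on a
#' 2x2 block `[[a, b], [c, d]]` the four outputs are `(a+b+c+d)/2`,
#' `(a+b-c-d)/2`, `(a-b+c-d)/2` and `(a-b-c+d)/2`.
#'
#' @param A numeric matrix with even height and width.
#' @param filters analysis pair from [haar_filters()] (or any orthonormal
#'   pair of equal-length filters).
#' @return list with numeric matrices `LL`, `LH`, `HL`, `HH`.
#' @export
dwt2_single_level <- function(A, filters = haar_filters()) {
  stopifnot(is.matrix(A))
  if (nrow(A) %% 2L != 0L || ncol(A) %% 2L != 0L) {
    stop(sprintf("both dimensions must be even, got %dx%d", nrow(A), ncol(A)))
  }
  A <- A * 1.0
  # row pass: filter along each row = along the column index -> transpose trick
  Lr <- t(filter_down(t(A), filters$h))
  Hr <- t(filter_down(t(A), filters$g))
  list(LL = filter_down(Lr, filters$h),
       LH = filter_down(Lr, filters$g),
       HL = filter_down(Hr, filters$h),
       HH = filter_down(Hr, filters$g))
}

# 1-D synthesis (adjoint of filter_down; exact inverse for orthonormal pairs)
filter_up <- function(y, f, n) {
  x <- matrix(0, n, ncol(y))
  base <- 2L * (seq_len(nrow(y)) - 1L)
  for (m in seq_along(f)) {
    idx <- ((base + m - 1L) %% n) + 1L
    # accumulate; idx values are distinct for each m with stride-2 bases
    x[idx, ] <- x[idx, ] + f[m] * y
  }
  x
}

#' Inverse of [dwt2_single_level()] (orthonormal filters only)
#'
#' @param bands list with `LL`, `LH`, `HL`, `HH` as produced by
#'   [dwt2_single_level()].
#' @inheritParams dwt2_single_level
#' @return the reconstructed matrix.
#' @export
idwt2_single_level <- function(bands, filters = haar_filters()) {
  h2 <- nrow(bands$LL) * 2L
  w2 <- ncol(bands$LL) * 2L
  Lr <- filter_up(bands$LL, filters$h, h2) + filter_up(bands$LH, filters$g, h2)
  Hr <- filter_up(bands$HL, filters$h, h2) + filter_up(bands$HH, filters$g, h2)
  t(filter_up(t(Lr), filters$h, w2)) + t(filter_up(t(Hr), filters$g, w2))
}

#' Multi-level 2-D wavelet decomposition
#'
#' Recursively applies [dwt2_single_level()] to the approximation band. Each
#' stage requires even dimensions (a 40x40 patch supports `levels <= 3`:
#' 40 -> 20 -> 10 -> 5). If a stage would see an odd dimension the call
#' errors, stating the maximum feasible level — unless `pad = TRUE`, in which
#' case the input is zero-padded up to the next multiple of `2^levels` with a
#' warning.
#'
#' @param A numeric matrix.
#' @param levels number of decomposition levels (>= 1).
#' @param filters analysis pair, default Haar.
#' @param pad zero-pad instead of erroring on infeasible sizes.
#' @return an object of class `"wavelet_decomposition"`: list with `levels`
#'   (each a list of `LH`, `HL`, `HH` detail bands, finest first), the final
#'   approximation `LL`, and the filter pair. Total coefficient count equals
#'   the (padded) pixel count.
#' @export
dwt2 <- function(A, levels = 3L, filters = haar_filters(), pad = FALSE) {
  stopifnot(is.matrix(A), levels >= 1L)
  feasible <- function(n) {  # max level with evenness at every stage
    k <- 0L
    while (n %% 2L == 0L) { n <- n %/% 2L; k <- k + 1L }
    k
  }
  maxlev <- min(feasible(nrow(A)), feasible(ncol(A)))
  if (maxlev < levels) {
    if (!pad) {
      stop(sprintf(
        "%dx%d supports at most %d decomposition level(s); requested %d (use pad = TRUE to zero-pad)",
        nrow(A), ncol(A), maxlev, levels))
    }
    m <- 2L^levels
    H <- as.integer(ceiling(nrow(A) / m) * m)
    W <- as.integer(ceiling(ncol(A) / m) * m)
    warning(sprintf("zero-padding %dx%d to %dx%d for %d levels",
                    nrow(A), ncol(A), H, W, levels))
    P <- matrix(0, H, W)
    P[seq_len(nrow(A)), seq_len(ncol(A))] <- A
    A <- P
  }
  detail <- vector("list", levels)
  cur <- A * 1.0
  for (k in seq_len(levels)) {
    b <- dwt2_single_level(cur, filters)
    detail[[k]] <- list(LH = b$LH, HL = b$HL, HH = b$HH)
    cur <- b$LL
  }
  structure(list(levels = detail, LL = cur, filters = filters),
            class = "wavelet_decomposition")
}

#' Names of the 5 wavelet features, in output order
#' @export
WAVELET_FEATURES <- c("mean", "sd", "skewness", "kurtosis", "mad")

#' Wavelet-coefficient statistics of a patch
#'
#' Pools every detail coefficient (LH, HL, HH across all levels) into one
#' sample and returns five statistics in fixed order: mean, standard
#' deviation (sample, `n - 1` denominator), skewness (Fisher g1,
#' bias-uncorrected), excess kurtosis (Fisher), and mean absolute deviation
#' about the mean. The approximation band is excluded: it carries the local
#' brightness, not the texture. A zero-variance coefficient sample (e.g. a
#' constant patch) yields skewness and kurtosis 0 with a warning.
#'
#' @inheritParams dwt2
#' @param patch integer or numeric matrix (typically a 40x40 ROI).
#' @return named numeric vector of length 5.
#' @export
wavelet_feature_vector <- function(patch, levels = 3L,
                                   filters = haar_filters()) {
  dec <- dwt2(patch, levels = levels, filters = filters, pad = TRUE)
  x <- unlist(lapply(dec$levels, function(l) c(l$LH, l$HL, l$HH)),
              use.names = FALSE)
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero-variance detail coefficients: skewness/kurtosis set to 0")
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  }
  c(mean = m,
    sd = if (n > 1) stats::sd(x) else 0,
    skewness = skew,
    kurtosis = kurt,
    mad = mean(abs(x - m)))
}
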