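# Independent brute-force oracles used to check the vectorized implementations.
# Each is written as a direct transcription of the defining formula/procedure,
# with no code shared with the package internals.

# ---- co-occurrence ----------------------------------------------------------

oracle_glcm_P <- function(q, d, angle, G, symmetric = TRUE) {
  offs <- list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0), `135` = c(-d, -d))
  o <- offs[[as.character(angle)]]
  counts <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) for (c in seq_len(ncol(q))) {
    r2 <- r + o[1]; c2 <- c + o[2]
    if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
      counts[q[r, c] + 1, q[r2, c2] + 1] <- counts[q[r, c] + 1, q[r2, c2] + 1] + 1
      if (symmetric) {
        counts[q[r2, c2] + 1, q[r, c] + 1] <- counts[q[r2, c2] + 1, q[r, c] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# the 13 features recomputed from an enumerated pair distribution
oracle_glcm_features <- function(P) {
  G <- nrow(P)
  i <- rep(0:(G - 1), times = G)   # row index of each cell
  j <- rep(0:(G - 1), each = G)
  p <- as.vector(P)
  mux <- sum(i * p); muy <- sum(j * p)
  sdx <- sqrt(sum((i - mux)^2 * p)); sdy <- sqrt(sum((j - muy)^2 * p))
  ent <- function(w) { w <- w[w > 0]; -sum(w * log(w)) }
  px <- rowSums(P); py <- colSums(P)
  pxy <- as.vector(outer(px, py))   # same column-major layout as p
  hxy1 <- -sum(ifelse(pxy > 0, p * log(pxy), 0))
  c(autocorrelation = sum(i * j * p),
    contrast = sum((i - j)^2 * p),
    correlation = if (sdx == 0 || sdy == 0) 0 else
      sum((i - mux) * (j - muy) * p) / (sdx * sdy),
    cluster_prominence = sum((i + j - mux - muy)^4 * p),
    cluster_shade = sum((i + j - mux - muy)^3 * p),
    energy = sum(p^2),
    dissimilarity = sum(abs(i - j) * p),
    homogeneity = sum(p / (1 + abs(i - j))),
    info_measure_corr1 = if (max(ent(px), ent(py)) == 0) 0 else
      (ent(p) - hxy1) / max(ent(px), ent(py)),
    maximum_probability = max(p),
    inverse_difference = sum(p / (1 + (i - j)^2)),
    inverse_difference_normalized = sum(p / (1 + abs(i - j) / G)),
    inverse_difference_moment_normalized = sum(p / (1 + (i - j)^2 / G^2)))
}

# ---- run lengths ------------------------------------------------------------

# walk every line from its start pixel, accumulating maximal runs
oracle_glrlm_R <- function(q, angle, G) {
  step <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `135` = c(-1, -1))[[as.character(angle)]]
  h <- nrow(q); w <- ncol(q)
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w
  R <- matrix(0, G, max(h, w))
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (inside(r - step[1], c - step[2])) next   # not a line start
    run_val <- q[r, c]; run_len <- 0
    rr <- r; cc <- c
    while (inside(rr, cc)) {
      if (q[rr, cc] == run_val) {
        run_len <- run_len + 1
      } else {
        R[run_val + 1, run_len] <- R[run_val + 1, run_len] + 1
        run_val <- q[rr, cc]; run_len <- 1
      }
      rr <- rr + step[1]; cc <- cc + step[2]
    }
    R[run_val + 1, run_len] <- R[run_val + 1, run_len] + 1
  }
  R
}

# ---- ROC / AUC --------------------------------------------------------------

oracle_auc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  s <- 0
  for (a in ps) for (b in ns) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(ps) * length(ns))
}

# ---- wavelets ---------------------------------------------------------------

# explicit orthogonal analysis matrix: rows are the shifted (periodic) filters
oracle_analysis_matrix <- function(n, filters) {
  W <- matrix(0, n, n)
  half <- n %/% 2
  for (k in seq_len(half)) for (m in seq_along(filters$h)) {
    idx <- ((2 * (k - 1) + m - 1) %% n) + 1
    W[k, idx] <- W[k, idx] + filters$h[m]
    W[half + k, idx] <- W[half + k, idx] + filters$g[m]
  }
  W
}

oracle_dwt2_single <- function(A, filters = haar_filters()) {
  Wr <- oracle_analysis_matrix(nrow(A), filters)
  Wc <- oracle_analysis_matrix(ncol(A), filters)
  B <- Wr %*% A %*% t(Wc)
  h <- nrow(A) %/% 2; w <- ncol(A) %/% 2
  list(LL = B[1:h, 1:w, drop = FALSE],
       LH = B[(h + 1):(2 * h), 1:w, drop = FALSE],
       HL = B[1:h, (w + 1):(2 * w), drop = FALSE],
       HH = B[(h + 1):(2 * h), (w + 1):(2 * w), drop = FALSE])
}

oracle_dwt2 <- function(A, levels, filters = haar_filters()) {
  details <- list()
  cur <- A
  for (k in seq_len(levels)) {
    b <- oracle_dwt2_single(cur, filters)
    details[[k]] <- b[c("LH", "HL", "HH")]
    cur <- b$LL
  }
  list(levels = details, LL = cur)
}

# ---- spatial filters --------------------------------------------------------

refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))

oracle_median3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (r in seq_len(h)) for (c in seq_len(w)) {
    vals <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      vals <- c(vals, img[refl(r + dr, h), refl(c + dc, w)])
    }
    out[r, c] <- sort(vals)[5]
  }
  out
}

oracle_gaussian <- function(img, sigma, L = 256) {
  r <- ceiling(3 * sigma)
  k1 <- exp(-((-r):r)^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + k1[di + r + 1] * k1[dj + r + 1] *
        img[refl(i + di, h), refl(j + dj, w)]
    }
    out[i, j] <- acc
  }
  pmax(pmin(round(out), L - 1), 0)
}

# ---- regional maxima --------------------------------------------------------

# morphological-reconstruction oracle: a pixel is on a regional maximum iff
# grayscale reconstruction of (img - 1) under img stays below img there
oracle_regional_maxima <- function(img) {
  h <- nrow(img); w <- ncol(img)
  dil8 <- function(m) {
    p <- matrix(-Inf, h + 2, w + 2)
    p[2:(h + 1), 2:(w + 1)] <- m
    out <- matrix(-Inf, h, w)
    for (dr in 0:2) for (dc in 0:2) {
      out <- pmax(out, p[(1 + dr):(h + dr), (1 + dc):(w + dc)])
    }
    out
  }
  rec <- img - 1
  repeat {
    nxt <- pmin(dil8(rec), img)
    if (all(nxt == rec)) break
    rec <- nxt
  }
  (img - rec) > 0
}

# ---- misc helpers -----------------------------------------------------------

random_patch <- function(h, w, L = 256, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:(L - 1), h * w, replace = TRUE), h, w)
}

# small synthetic study used by the cheaper end-to-end tests
small_config <- function(seed = 11L) {
  study_config(class_counts = c(abscess = 4, cyst = 4, tumor = 4, normal = 4),
               image_shape = c(120, 160), seed = seed)
}
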