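test_that("quantize bins uniformly with the clip rule", {
  expect_equal(quantize(matrix(c(0, 255, 128, 32), 2), G = 8)[1:4],
               c(0L, 7L, 4L, 1L))
  expect_error(quantize(matrix(0, 2, 2), G = 1), "G >= 2")
})

test_that("compute_glcm on hand-enumerable patches", {
  # constant patch: single nonzero cell on the diagonal
  g <- compute_glcm(matrix(100L, 4, 4))
  expect_equal(sum(g$P), 1)
  expect_equal(g$P[4, 4], 1)       # 100 quantizes to level 3 (cell 4)

  # 2x2 [[0,1],[0,1]] at G=2, horizontal, symmetric: the two pairs (0,1)
  p <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # column-major: rows are [0,1],[0,1]
  g <- compute_glcm(p, d = 1, angles = 0, G = 2, quantized = TRUE)
  expect_equal(g$P, matrix(c(0, .5, .5, 0), 2, 2))
  expect_error(compute_glcm(matrix(0L, 1, 1), angles = 0, quantized = TRUE, G = 2),
               "no valid pixel pairs")
})

test_that("printed-formula features on the anti-diagonal 2-level case", {
  P <- matrix(c(0, .5, .5, 0), 2, 2)
  g <- structure(list(P = P, G = 2L, px = c(.5, .5), py = c(.5, .5),
                      mux = .5, muy = .5, sdx = .5, sdy = .5),
                 class = "glcm")
  expect_equal(glcm_energy(g), 0.5)
  expect_equal(glcm_contrast(g), 1)
  expect_equal(glcm_correlation(g), -1)
  expect_equal(glcm_homogeneity(g), 0.5)

  # perfectly diagonal two-level matrix: correlation +1
  gd <- compute_glcm(matrix(c(0L, 0L, 1L, 1L), 2, 2), d = 1, angles = 90,
                     G = 2, quantized = TRUE)
  expect_equal(gd$P, diag(2) / 2)
  expect_equal(glcm_correlation(gd), 1)

  # uniform P over all cells: energy 1/G^2; 2-level homogeneity 0.75
  gu <- structure(list(P = matrix(.25, 2, 2), G = 2L), class = "glcm")
  expect_equal(glcm_energy(gu), 0.25)
  expect_equal(glcm_homogeneity(gu), 0.75)

  # degenerate constant patch: correlation 0 with a warning
  gc <- compute_glcm(matrix(5L, 3, 3))
  expect_warning(v <- glcm_correlation(gc), "degenerate")
  expect_equal(v, 0)
  expect_equal(glcm_energy(gc), 1)      # "energy of a constant image is 1"
  expect_equal(glcm_contrast(gc), 0)
  expect_equal(glcm_homogeneity(gc), 1)
})

test_that("matrix and all 13 features match brute-force pair enumeration", {
  for (seed in 1:50) {
    q <- random_patch(8, 8, L = 8, seed = seed)  # already in 0..7
    for (a in c(0, 45, 90, 135)) {
      g <- compute_glcm(q, d = 1, angles = a, G = 8, quantized = TRUE)
      expect_equal(g$P, oracle_glcm_P(q, 1, a, 8), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
    got <- glcm_feature_vector(q, G = 8, quantized = TRUE)
    want <- rowMeans(sapply(c(0, 45, 90, 135), function(a) {
      oracle_glcm_features(oracle_glcm_P(q, 1, a, 8))
    }))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("GLCM invariants: normalization, symmetry, ranges, rotation", {
  for (seed in 1:10) {
    q <- random_patch(10, 10, L = 8, seed = seed)
    g <- compute_glcm(q, G = 8, quantized = TRUE)
    expect_equal(sum(g$P), 1, tolerance = 1e-9)
    expect_equal(g$P, t(g$P))
    f <- glcm_feature_vector(q, G = 8, quantized = TRUE)
    expect_length(f, 13)
    expect_named(f, GLCM_FEATURES)
    expect_true(f["energy"] > 0 && f["energy"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    expect_true(abs(f["correlation"]) <= 1 + 1e-12)
    expect_gte(f["contrast"], 0)
    # contrast as sum over |i-j| bands equals sum (i-j)^2 P
    expect_equal(unname(f["contrast"]),
                 mean(sapply(c(0, 45, 90, 135), function(a) {
                   P <- oracle_glcm_P(q, 1, a, 8)
                   sum(sapply(0:7, function(n) {
                     n^2 * sum(P[abs(outer(0:7, 0:7, "-")) == n])
                   }))
                 })), tolerance = 1e-10)
    # rotating the patch 90 degrees leaves the angle-averaged vector unchanged
    qr <- t(q)[ncol(q):1, ]
    expect_equal(f, glcm_feature_vector(qr, G = 8, quantized = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("feature vector propagates and averages over requested angles", {
  q <- random_patch(6, 6, L = 8, seed = 99)
  f2 <- glcm_feature_vector(q, angles = c(0, 90), G = 8, quantized = TRUE)
  manual <- (glcm_feature_vector(q, angles = 0, G = 8, quantized = TRUE) +
             glcm_feature_vector(q, angles = 90, G = 8, quantized = TRUE)) / 2
  expect_equal(f2, manual, tolerance = 1e-12)
})
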