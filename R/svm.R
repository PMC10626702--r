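# Internal soft-margin kernel SVM solver.
#
# Solves the standard C-SVM dual
#   min_a  1/2 sum_ij a_i a_j y_i y_j K_ij - sum_i a_i
#   s.t.   0 <= a_i <= C,  sum_i a_i y_i = 0
# by sequential minimal optimization with maximal-violating-pair working-set
# selection. Fully deterministic: no randomness enters the solver, so refits
# on identical data reproduce identical models bit for bit.

rbf_kernel <- function(X, Y, gamma) {
  # squared Euclidean distances via the expansion |x|^2 + |y|^2 - 2 x.y
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

kernel_matrix <- function(X, Y, kernel, gamma) {
  switch(kernel,
         rbf = rbf_kernel(X, Y, gamma),
         linear = tcrossprod(X, Y),
         stop("unknown kernel: ", kernel))
}

smo_solve <- function(K, y, C = 1, eps = 1e-3, max_iter = NULL) {
  n <- length(y)
  if (is.null(max_iter)) max_iter <- max(10000L, 200L * n)
  alpha <- numeric(n)
  grad <- rep(-1, n)                      # gradient of the dual at alpha = 0
  Q <- K * tcrossprod(y)                  # Q_ij = y_i y_j K_ij
  for (iter in seq_len(max_iter)) {
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    low <- (y < 0 & alpha < C) | (y > 0 & alpha > 0)
    if (!any(up) || !any(low)) break
    viol <- -y * grad
    i <- which(up)[which.max(viol[up])]
    j <- which(low)[which.min(viol[low])]
    if (viol[i] - viol[j] < eps) break
    a2 <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (a2 <= 0) a2 <- 1e-12
    delta <- (viol[i] - viol[j]) / a2
    s <- y[i] * alpha[i] + y[j] * alpha[j]   # conserved by the equality constraint
    ai <- alpha[i] + y[i] * delta
    ai <- min(max(ai, 0), C)
    aj <- y[j] * (s - y[i] * ai)
    aj <- min(max(aj, 0), C)
    ai <- y[i] * (s - y[j] * aj)
    ai <- min(max(ai, 0), C)
    dai <- ai - alpha[i]; daj <- aj - alpha[j]
    if (abs(dai) < 1e-14 && abs(daj) < 1e-14) break
    grad <- grad + Q[, i] * dai + Q[, j] * daj
    alpha[i] <- ai; alpha[j] <- aj
  }
  # intercept from the KKT conditions: v_t = y_t - u_t is the b making row t
  # sit exactly on the margin; free SVs pin it, bound points bracket it
  u <- as.vector(K %*% (alpha * y))
  v <- y - u
  free <- alpha > 1e-8 & alpha < C - 1e-8
  if (any(free)) {
    b <- mean(v[free])
  } else {
    lo <- suppressWarnings(max(v[(alpha <= 1e-8 & y < 0) | (alpha >= C - 1e-8 & y > 0)]))
    hi <- suppressWarnings(min(v[(alpha <= 1e-8 & y > 0) | (alpha >= C - 1e-8 & y < 0)]))
    if (!is.finite(lo)) lo <- hi
    if (!is.finite(hi)) hi <- lo
    b <- (lo + hi) / 2
  }
  list(alpha = alpha, b = b)
}
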