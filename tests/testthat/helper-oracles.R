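# Independent reference implementations used as oracles. These deliberately
# use the most direct (brute-force / closed-form) route, not the package's
# own code paths.

# one-component PLS1 by the textbook algorithm
pls1_oracle <- function(X, y01) {
  X <- as.matrix(X)
  yc <- y01 - mean(y01)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(X %*% w)
  cq <- sum(t * yc) / sum(t^2)
  b <- unname(w * cq)
  list(b = b, fitted = mean(y01) + drop(X %*% b))
}

# sliding-window RMS by explicit looping (truncated windows at the edges)
rms_brute <- function(x, rate, window_s = 0.05) {
  k <- round(window_s * rate)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - half):min(n, i + half)
    sqrt(mean(x[idx]^2))
  }, numeric(1))
}

# exact PCA by eigendecomposition of the cross-product (input pre-centred)
eigen_pca_oracle <- function(X, k) {
  X <- as.matrix(X)
  e <- eigen(crossprod(X), symmetric = TRUE)
  loadings <- e$vectors[, seq_len(k), drop = FALSE]
  list(
    scores = X %*% loadings,
    loadings = loadings,
    r2 = e$values[seq_len(k)] / sum(e$values)
  )
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(pooled), nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Wilcoxon signed-rank p by enumeration of sign patterns
wsr_exact_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# two-sided Fisher exact p by summing hypergeometric point probabilities
fisher_exact_oracle <- function(a, b, c, d) {
  m <- a + b # row 1 total
  n2 <- c + d # row 2 total
  k <- a + c # column 1 total
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
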