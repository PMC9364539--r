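# Independent brute-force oracles. These re-derive each statistic from its
# definition with naive loops, deliberately sharing no code with the package.

oracle_bicor <- function(x, y) {
  weigh <- function(v) {
    med <- median(v)
    madv <- median(abs(v - med))
    if (madv == 0) {        # Pearson fallback branch of the definition
      c <- v - mean(v)
      return(c / sqrt(sum(c^2)))
    }
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      u <- (v[i] - med) / (9 * madv)
      w <- if (abs(u) < 1) (1 - u^2)^2 else 0
      out[i] <- (v[i] - med) * w
    }
    out / sqrt(sum(out^2))
  }
  sum(weigh(x) * weigh(y))
}

oracle_hoeffding <- function(x, y) {
  n <- length(x)
  R <- rank(x); S <- rank(y)
  Q <- numeric(n)
  for (i in 1:n) {
    q <- 1
    for (j in 1:n) {
      if (j == i) next
      cx <- if (x[j] < x[i]) 1 else if (x[j] == x[i]) 0.5 else 0
      cy <- if (y[j] < y[i]) 1 else if (y[j] == y[i]) 0.5 else 0
      q <- q + cx * cy
    }
    Q[i] <- q
  }
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

oracle_tom <- function(a) {
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

oracle_adjacency <- function(X, beta) {
  # X genes x samples; element-wise Pearson from first principles
  n <- nrow(X)
  a <- matrix(1, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    xi <- X[i, ] - mean(X[i, ]); xj <- X[j, ] - mean(X[j, ])
    r <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    a[i, j] <- abs(r)^beta
  }
  a
}

oracle_bh <- function(p) {
  # textbook step-up: q_(i) = min_{k >= i} p_(k) * m / k, capped at 1
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

oracle_mwu_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  u
}

oracle_mwu_exact_p <- function(x, y) {
  # exact two-sided p by enumerating all assignments of the pooled values
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- combn(length(pooled), n1)
  obs <- oracle_mwu_u(x, y)
  n2 <- length(y)
  mu <- n1 * n2 / 2
  cnt <- 0
  for (k in seq_len(ncol(idx))) {
    u <- oracle_mwu_u(pooled[idx[, k]], pooled[-idx[, k]])
    if (abs(u - mu) >= abs(obs - mu) - 1e-12) cnt <- cnt + 1
  }
  cnt / ncol(idx)
}

oracle_hyper_tail <- function(k, K, N, n) {
  # P(X >= k) by direct summation of the pmf from binomial coefficients
  tot <- 0
  for (x in k:min(K, n))
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  tot
}

oracle_lstsq <- function(X, y) {
  # normal equations via SVD pseudo-inverse
  sv <- svd(X)
  as.numeric(sv$v %*% ((t(sv$u) %*% y) / sv$d))
}

oracle_ks_sup <- function(x, pooled) {
  # sup |ECDF_x - ECDF_pooled| by scanning every pooled value
  vals <- sort(unique(pooled))
  mx <- 0
  for (v in vals) {
    d <- abs(mean(x <= v) - mean(pooled <= v))
    if (d > mx) mx <- d
  }
  mx
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# Method-of-moments variance components for a balanced two-way random model
# with interaction (expected mean squares), truncated at zero.
oracle_mom_components <- function(y, strain, diet) {
  a <- length(unique(strain)); b <- length(unique(diet))
  r <- length(y) / (a * b)
  an <- anova(lm(y ~ factor(strain) * factor(diet)))
  mse <- an["Residuals", "Mean Sq"]
  ms_i <- an[3, "Mean Sq"]
  v_i <- (ms_i - mse) / r
  v_s <- (an[1, "Mean Sq"] - ms_i) / (r * b)
  v_d <- (an[2, "Mean Sq"] - ms_i) / (r * a)
  pmax(c(strain = v_s, diet = v_d, interaction = v_i, resid = mse), 0)
}
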