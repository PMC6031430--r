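# Independent brute-force reference implementations. These stay deliberately
# naive (double loops, exhaustive enumeration) and are never used by the
# package code they check.

# Shannon entropy in bits by explicit loop.
oracle_entropy <- function(p) {
  h <- 0
  for (i in seq_along(p)) if (p[i] > 0) h <- h - p[i] * log2(p[i])
  h
}

# KL divergence in bits by explicit loop.
oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  s
}

# Two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of all
# choose(n, nx) assignments of the pooled ranks (ties allowed via midranks).
oracle_wilcoxon <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nx * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Plug-in mutual information (bits) from a joint count table by double loop.
oracle_mi_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  mi
}

# Plug-in MI from per-trial cell densities + labels, by double loop over
# (cell, label); mirrors the integral the package discretizes.
oracle_mi_assignments <- function(pre, labels) {
  labs <- sort(unique(labels))
  p_l <- sapply(labs, function(l) mean(labels == l))
  cond <- sapply(labs, function(l) {
    m <- rowMeans(pre[, labels == l, drop = FALSE])
    m / sum(m)
  })
  marg <- as.vector(cond %*% p_l)
  mi <- 0
  for (k in seq_along(labs)) for (i in seq_len(nrow(pre))) {
    if (cond[i, k] > 0 && marg[i] > 0)
      mi <- mi + p_l[k] * cond[i, k] * log2(cond[i, k] / marg[i])
  }
  mi
}

# Per-pixel variance of a stack by explicit loop (posture pixel selection).
oracle_column_variance <- function(X) {
  apply(X, 2, function(v) sum((v - mean(v))^2) / (length(v) - 1))
}
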