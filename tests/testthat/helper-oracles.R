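# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain, slow, loop-based reference code,
# sharing no logic with the package internals.

# Minimal within-cluster SSE over all partitions of the rows of X into
# exactly k nonempty blocks, by exhaustive enumeration of label vectors.
oracle_best_sse <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n <= 9)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- rep(TRUE, nrow(grid))
  for (c in seq_len(k)) keep <- keep & rowSums(grid == c) > 0L
  grid <- grid[keep, , drop = FALSE]
  total <- sum(X^2)
  sse <- rep(total, nrow(grid))
  for (c in seq_len(k)) {
    Ind <- grid == c
    nc <- rowSums(Ind)
    Sx <- Ind %*% X
    sse <- sse - rowSums(Sx^2) / nc
  }
  min(sse)
}

# Silhouette by direct evaluation of the definition, point by point.
oracle_mean_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      members <- which(labels == cl)
      b <- min(b, mean(vapply(members, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Likelihood-ratio (G) statistic of an r x c contingency table computed
# directly from observed and independence-expected counts.
oracle_g_statistic <- function(m) {
  m <- as.matrix(m)
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  2 * sum(ifelse(m > 0, m * log(m / E), 0))
}
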