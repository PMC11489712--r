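# Independent oracles used to freeze expected values.

# Minimum external path length over all binary trees with n leaves, by
# dynamic programming over the size of the first subtree.
minMeanLeafDepth <- function(n) {
  E <- rep(NA_real_, n)
  E[1] <- 0
  if (n >= 2) for (m in 2:n)
    E[m] <- m + min(vapply(1:(m %/% 2),
                           function(k) E[k] + E[m - k], numeric(1)))
  E[n] / n
}

# Mean leaf depth of the caterpillar tree with n leaves: depths are
# 1, 2, ..., n-1 with the deepest depth occurring twice.
caterpillarMeanDepth <- function(n) (sum(seq_len(n - 1)) + (n - 1)) / n

# Brute-force Pearson statistic.
chisqStatOracle <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Pooled two-proportion z recomputed from first principles.
zPooledOracle <- function(x1, n1, x2, n2) {
  p <- (x1 + x2) / (n1 + n2)
  ((x1 / n1) - (x2 / n2)) / sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
}

# Exact two-sided Mann-Whitney p by enumeration over all interleavings,
# using midranks so tied data are handled.
mwuExactOracle <- function(a, b) {
  nA <- length(a)
  N <- nA + length(b)
  r <- rank(c(a, b))
  mu <- nA * length(b) / 2
  uObs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  us <- utils::combn(N, nA, function(ix) sum(r[ix]) - nA * (nA + 1) / 2)
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}
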