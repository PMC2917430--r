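# Independent brute-force oracles used to validate the fast implementations.

# Literal running-sum walk over the ranked list: +1/k at hits, -1/(n-k)
# elsewhere, maximum prefix sum including the empty prefix.
oracle_ks <- function(positions, n, k = length(positions)) {
  step <- rep(-1 / (n - k), n)
  step[positions] <- 1 / k
  max(0, cumsum(step))
}

# Textbook Benjamini-Hochberg step-up, spelled out.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(p[ord[i:m]] * m / seq(i, m)))
  }
  q
}

# Pooled-variance two-sample t statistic, from first principles.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Pearson correlation from covariance arithmetic, avoiding stats::cor.
oracle_cor <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# A small positive matrix with gene/sample names.
toy_matrix <- function(values, ids = NULL) {
  m <- values
  rownames(m) <- ids %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
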