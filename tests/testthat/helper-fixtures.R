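# Shared fixture builders; everything is generated in code, nothing stored.

# two (or k) Gaussian blobs as an omics_layer
blob_layer <- function(n = 30, p = 20, k = 2, shift = 4, seed = 1,
                       name = "blobs") {
  set.seed(seed)
  labels <- rep_len(seq_len(k), n)
  X <- matrix(rnorm(n * p), n, p) + shift * (labels - (k + 1) / 2)
  rownames(X) <- sprintf("S%03d", seq_len(n))
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(layer = omics_layer(X, name), labels = stats::setNames(labels, rownames(X)))
}

# noisy block affinity matrix: within-block weight 1 +/- jitter, between `lo`
block_affinity <- function(block_sizes, lo = 0.05, jitter = 0.05, seed = 1) {
  set.seed(seed)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  n <- length(blocks)
  W <- matrix(lo, n, n)
  same <- outer(blocks, blocks, "==")
  W[same] <- 1 + runif(sum(same), -jitter, jitter)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  rownames(W) <- colnames(W) <- sprintf("S%03d", seq_len(n))
  list(W = affinity_network(W), blocks = stats::setNames(blocks, rownames(W)))
}

# independent reimplementation of the quadratic weighted kappa, by explicit
# loops over the full category grid (oracle for the vectorized version)
kappa_bruteforce <- function(pred, actual, C = 3) {
  keep <- !is.na(pred) & !is.na(actual)
  pred <- pred[keep]; actual <- actual[keep]
  num <- 0; den <- 0
  n <- length(pred)
  for (i in 0:(C - 1)) for (j in 0:(C - 1)) {
    w <- (i - j)^2 / (C - 1)^2
    O <- sum(pred == i & actual == j)
    E <- sum(pred == i) * sum(actual == j) / n
    num <- num + w * O
    den <- den + w * E
  }
  if (den == 0) return(1)
  1 - num / den
}

# contingency-table ARI computed step by step (oracle for cluster_concordance)
ari_bruteforce <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}
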