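test_that("affinity kernel matches the hand-evaluated local-scaling formula", {
  # 3 samples, pairwise distances d12 = 1, d13 = 2, d23 = 2, K = 1, alpha = 0.5
  d <- matrix(c(0, 1, 2,
                1, 0, 2,
                2, 2, 0), 3, 3)
  W <- affinity_kernel(d, K = 1, alpha = 0.5)
  # mu = (1, 1, 2); eps12 = (1+1+1)/3 = 1; eps13 = eps23 = (1+2+2)/3 = 5/3
  expect_equal(W[1, 2], exp(-1 / (0.5 * 1)))
  expect_equal(W[1, 3], exp(-4 / (0.5 * 5 / 3)))
  expect_equal(W[2, 3], exp(-4 / (0.5 * 5 / 3)))
  expect_equal(diag(W), rep(1, 3))       # d = 0 pairs are maximal
  expect_equal(W, t(W))
})

test_that("affinity_from_layer: identical samples get similarity 1, degenerate features dropped", {
  set.seed(4)
  X <- matrix(rnorm(8 * 6), 8, 6)
  X[2, ] <- X[1, ]                       # duplicate pair
  X <- cbind(X, const = 1)               # zero-variance feature
  rownames(X) <- sprintf("S%d", 1:8)
  colnames(X)[1:6] <- sprintf("f%d", 1:6)
  ly <- omics_layer(X, "toy")
  expect_warning(net <- affinity_from_layer(ly, snf_params(K = 3)),
                 "zero-variance")
  expect_equal(net$W["S1", "S2"], 1)
  ident <- omics_layer(matrix(1:0, 4, 2, byrow = TRUE,
                              dimnames = list(sprintf("S%d", 1:4), c("a", "b"))) * 0 + 5,
                       "flat")
  expect_error(suppressWarnings(affinity_from_layer(ident, snf_params(K = 2))),
               "identical")
})

test_that("status and local matrices are row-stochastic with the hand-normalized toy", {
  W <- matrix(c(0, 4, 2, 1,
                4, 0, 3, 2,
                2, 3, 0, 5,
                1, 2, 5, 0), 4, 4,
              dimnames = list(sprintf("S%d", 1:4), sprintf("S%d", 1:4)))
  ps <- status_and_local(affinity_network(W), K = 2)
  expect_equal(rowSums(ps$P), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rowSums(ps$S), rep(1, 4), ignore_attr = TRUE)
  expect_equal(diag(ps$P), rep(0.5, 4), ignore_attr = TRUE)
  # hand: row 1 off-diag sum = 7 -> P[1,2] = 4/14; S row 1 keeps the K = 2
  # largest neighbours {S2, S3}: 4/6 and 2/6, S4 zeroed
  expect_equal(ps$P[1, 2], 4 / 14)
  expect_equal(unname(ps$S[1, ]), c(0, 4 / 6, 2 / 6, 0))
  expect_equal(diag(ps$S), rep(0, 4), ignore_attr = TRUE)
  # K = n - 1: S equals row-normalized W with zero diagonal
  ps_full <- status_and_local(affinity_network(W), K = 3)
  expect_equal(ps_full$S, W / rowSums(W), ignore_attr = TRUE)
})

test_that("fusion preserves row-stochasticity, symmetry and sample order", {
  bl1 <- blob_layer(n = 24, p = 15, seed = 1, name = "a")
  bl2 <- blob_layer(n = 24, p = 15, seed = 2, name = "b")
  ps <- lapply(list(bl1$layer, bl2$layer), function(l)
    status_and_local(affinity_from_layer(l, snf_params(K = 8)), K = 8))
  fused <- snf_fuse(ps, t = 10)
  expect_equal(max(abs(fused$W - t(fused$W))), 0)
  # per-iteration status matrices are exactly row-stochastic (asserted inside
  # snf_fuse); the final symmetrized mean stays near-stochastic
  expect_equal(rowSums(fused$W), rep(1, 24), ignore_attr = TRUE,
               tolerance = 0.05)
  # order mismatch is an error, not a silent reorder
  ps_bad <- ps
  perm <- c(2:24, 1)
  ps_bad[[2]]$P <- ps_bad[[2]]$P[perm, perm]
  ps_bad[[2]]$S <- ps_bad[[2]]$S[perm, perm]
  expect_error(snf_fuse(ps_bad, t = 2), "order mismatch")
})

test_that("fusion is permutation-equivariant", {
  bl1 <- blob_layer(n = 18, p = 10, seed = 3, name = "a")
  bl2 <- blob_layer(n = 18, p = 10, seed = 4, name = "b")
  mk <- function(l) status_and_local(affinity_from_layer(l, snf_params(K = 6)), K = 6)
  fused <- snf_fuse(list(mk(bl1$layer), mk(bl2$layer)), t = 5)
  set.seed(9)
  perm <- sample(18)
  permute_layer <- function(bl) omics_layer(bl$layer$values[perm, ], bl$layer$layer_name)
  fused_p <- snf_fuse(list(mk(permute_layer(bl1)), mk(permute_layer(bl2))), t = 5)
  expect_equal(fused_p$W, fused$W[perm, perm], tolerance = 1e-12)
})

test_that("identical input layers are a fixed point of fusion up to label permutation", {
  bl <- blob_layer(n = 25, p = 30, k = 2, shift = 2, seed = 3)
  net <- affinity_from_layer(bl$layer, snf_params(K = 10))
  single <- spectral_cluster(net, 2, seed = 1)
  ps <- status_and_local(net, K = 10)
  for (tt in c(1, 5, 25)) {
    fused <- snf_fuse(list(ps, ps, ps), t = tt)
    lab <- spectral_cluster(fused, 2, seed = 1)
    expect_equal(cluster_concordance(lab, single)$agreement, 1)
  }
})

test_that("spectral clustering recovers exact and noisy blocks", {
  # exact block-diagonal: two disconnected components
  W <- matrix(0, 6, 6, dimnames = list(sprintf("S%d", 1:6), sprintf("S%d", 1:6)))
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  expect_warning(lab <- spectral_cluster(affinity_network(W), 2, seed = 1),
                 "disconnected")
  expect_equal(cluster_concordance(lab, rep(1:2, each = 3))$ari, 1)
  # noisy 3-block affinity: perfect recovery across seeds
  for (s in 1:10) {
    ba <- block_affinity(c(12, 10, 8), seed = s)
    lab <- spectral_cluster(ba$W, 3, seed = s)
    expect_equal(cluster_concordance(lab, ba$blocks)$ari, 1)
  }
  expect_error(spectral_cluster(block_affinity(c(3, 3))$W, 10), "k must be")
})

test_that("spectral clustering is deterministic under a fixed seed", {
  ba <- block_affinity(c(10, 10, 10), jitter = 0.3, seed = 2)
  expect_identical(spectral_cluster(ba$W, 3, seed = 42),
                   spectral_cluster(ba$W, 3, seed = 42))
})

test_that("eigengap selection finds block counts and flags structureless graphs", {
  ba <- block_affinity(c(12, 10, 8), seed = 1)
  k <- estimate_k_eigengap(ba$W, k_max = 8)
  expect_equal(as.integer(k), 3)
  expect_false(attr(k, "weak"))
  # complete graph: no structure, k = 2 by tie-break toward small k, weak gap
  n <- 12
  Wc <- matrix(1, n, n, dimnames = list(sprintf("S%d", 1:n), sprintf("S%d", 1:n)))
  k2 <- estimate_k_eigengap(affinity_network(Wc), k_max = 6)
  expect_equal(as.integer(k2), 2)
  expect_true(attr(k2, "weak"))
})
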