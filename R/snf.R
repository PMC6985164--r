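#' Parameters for similarity network fusion
#'
#' @param K number of nearest neighbours used for the local kernel bandwidth
#'   and the truncated similarity matrix (default 24).
#' @param alpha kernel bandwidth multiplier (> 0; 0.3--0.8 recommended,
#'   default 0.7).
#' @param t number of cross-diffusion iterations (default 25).
#' @return an `snf_params` list.
#' @export
snf_params <- function(K = 24, alpha = 0.7, t = 25) {
  stopifnot(K >= 1, alpha > 0, t >= 1)
  structure(list(K = as.integer(K), alpha = alpha, t = as.integer(t)),
            class = "snf_params")
}

#' Construct an affinity network
#'
#' Symmetric nonnegative sample x sample similarity matrix.
#'
#' @param W numeric matrix.
#' @param sample_ids optional ids (defaults to rownames).
#' @return an `affinity_network` object.
#' @export
affinity_network <- function(W, sample_ids = rownames(W)) {
  W <- as.matrix(W)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(W)))
  if (max(abs(W - t(W))) > 1e-10) stop("W must be symmetric (tolerance 1e-10)")
  if (any(W < 0)) stop("W must be nonnegative")
  dimnames(W) <- list(sample_ids, sample_ids)
  structure(list(W = W, sample_ids = sample_ids), class = "affinity_network")
}

#' @export
print.affinity_network <- function(x, ...) {
  cat(sprintf("<affinity_network: %d samples>\n", nrow(x$W)))
  invisible(x)
}

#' Patient similarity network from one omics layer
#'
#' Standardizes the layer per feature (after mean imputation of missing
#' values), computes Euclidean distances and applies the locally scaled
#' exponential kernel
#' \deqn{W_{ij} = \exp(-d^2_{ij} / (\alpha\,\varepsilon_{ij})),}
#' where \eqn{\varepsilon_{ij}} is the mean of: the average distance from i to
#' its K nearest neighbours, the same for j, and \eqn{d_{ij}} itself.
#'
#' @param layer an [omics_layer()].
#' @param params an [snf_params()].
#' @return an [affinity_network()].
#' @export
affinity_from_layer <- function(layer, params = snf_params()) {
  stopifnot(inherits(layer, "omics_layer"), inherits(params, "snf_params"))
  n <- nrow(layer$values)
  if (n < params$K + 1)
    stop(sprintf("need at least K+1 = %d samples, got %d", params$K + 1, n))
  X <- standardize_matrix(impute_missing(layer$values))
  if (ncol(X) == 0) stop("all samples identical: zero kernel bandwidth")
  W <- affinity_kernel(row_dist(X), params$K, params$alpha)
  affinity_network(W, layer$sample_ids)
}

#' Locally scaled exponential affinity kernel on a distance matrix
#'
#' \eqn{W_{ij} = \exp(-d_{ij}^2 / (\alpha\,\varepsilon_{ij}))} with
#' \eqn{\varepsilon_{ij} = (\mu_i + \mu_j + d_{ij})/3}, where \eqn{\mu_i} is
#' the mean distance from i to its K nearest neighbours (self excluded).
#' Pairs at distance zero (including the diagonal) get similarity 1.
#'
#' @param d symmetric nonnegative distance matrix.
#' @param K neighbour count for the local bandwidth.
#' @param alpha bandwidth multiplier.
#' @return symmetric similarity matrix.
#' @export
affinity_kernel <- function(d, K, alpha) {
  n <- nrow(d)
  if (K > n - 1) stop("K must be < number of samples")
  if (max(d) <= 0) stop("all samples identical: zero kernel bandwidth")
  mu <- vapply(seq_len(n), function(i) {
    r <- d[i, -i]
    mean(sort(r)[seq_len(K)])
  }, numeric(1))
  eps <- (outer(mu, mu, "+") + d) / 3
  W <- exp(-d^2 / (alpha * eps))
  W[d == 0] <- 1  # identical samples (and the diagonal): maximal similarity
  (W + t(W)) / 2
}

# Status (P) normalization: off-diagonal entries carry half the row mass,
# the diagonal carries the other half.  Rows sum to 1 exactly.
status_normalize <- function(W) {
  n <- nrow(W)
  off <- W
  diag(off) <- 0
  rs <- rowSums(off)
  if (any(rs <= 0)) {
    bad <- rownames(W)[rs <= 0]
    stop(sprintf("isolated sample(s) with zero similarity to all others: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  P <- off / (2 * rs)
  diag(P) <- 1 / 2
  P
}

#' Global status matrix P and local KNN-truncated matrix S
#'
#' P is the full row-stochastic status matrix: off-diagonal
#' \eqn{P_{ij} = W_{ij} / (2\sum_{k\neq i} W_{ik})} and \eqn{P_{ii} = 1/2}.
#' S keeps only each sample's K nearest neighbours (self excluded, diagonal
#' zero) and row-normalizes over that neighbour set. Every row of both sums
#' to 1.
#'
#' @param network an [affinity_network()].
#' @param K neighbour count.
#' @return list with elements `P` and `S`.
#' @export
status_and_local <- function(network, K) {
  stopifnot(inherits(network, "affinity_network"), K >= 1)
  W <- network$W
  n <- nrow(W)
  if (K > n - 1) stop("K must be < n_samples")
  P <- status_normalize(W)
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- 0
    nbr <- order(w, decreasing = TRUE)[seq_len(K)]
    tot <- sum(w[nbr])
    if (tot <= 0)
      stop(sprintf("sample %s has zero similarity to its neighbour set",
                   rownames(W)[i]))
    S[i, nbr] <- w[nbr] / tot
  }
  list(P = P, S = S)
}

#' Fuse per-layer similarity networks by cross-diffusion
#'
#' Iterates, for each layer v, \eqn{P_v \leftarrow S_v \bar P_{-v} S_v^T}
#' (with \eqn{\bar P_{-v}} the mean status matrix of the other layers), then
#' re-symmetrizes and renormalizes to status form, for `t` iterations; the
#' fused network is the elementwise mean of the final status matrices,
#' symmetrized. Row-stochasticity is asserted at every iteration.
#'
#' @param layers_ps list of `list(P =, S =)` per layer, as produced by
#'   [status_and_local()]; all must share the same sample ordering.
#' @param t number of iterations.
#' @return an [affinity_network()] of the fused similarities.
#' @export
snf_fuse <- function(layers_ps, t = 25) {
  L <- length(layers_ps)
  if (L < 2) stop("need at least 2 layers to fuse")
  ids <- rownames(layers_ps[[1]]$P)
  for (lp in layers_ps) {
    if (!identical(rownames(lp$P), ids))
      stop("sample order mismatch across layers (no silent reordering)")
  }
  Ps <- lapply(layers_ps, `[[`, "P")
  Ss <- lapply(layers_ps, `[[`, "S")
  for (it in seq_len(t)) {
    new_Ps <- vector("list", L)
    for (v in seq_len(L)) {
      Pbar <- Reduce(`+`, Ps[-v]) / (L - 1)
      upd <- Ss[[v]] %*% Pbar %*% t(Ss[[v]])
      upd <- (upd + t(upd)) / 2
      new_Ps[[v]] <- status_normalize(upd)
      stopifnot(max(abs(rowSums(new_Ps[[v]]) - 1)) < 1e-9)
    }
    Ps <- new_Ps
  }
  fused <- Reduce(`+`, Ps) / L
  fused <- (fused + t(fused)) / 2
  affinity_network(fused, ids)
}

# Connected components of the nonzero-weight graph (simple BFS).
# Only exact zeros count as absent edges: the exponential kernel never
# produces them, so this flags genuinely block-structured inputs only.
graph_components <- function(W, eps = 0) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      nbr <- which(W[i, ] > eps & comp == 0L)
      comp[nbr] <- cur
      queue <- c(queue, nbr)
    }
  }
  comp
}

#' Spectral clustering of an affinity network
#'
#' Embeds samples in the top-k eigenvectors of the symmetric normalized
#' Laplacian \eqn{L = I - D^{-1/2} W D^{-1/2}} (rows unit-normalized) and
#' clusters the embedding with k-means (100 restarts, best inertia).
#' Deterministic under a fixed seed.
#'
#' @param network an [affinity_network()].
#' @param k number of clusters (>= 2).
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return named integer label vector (a subtype assignment).
#' @export
spectral_cluster <- function(network, k, seed = 1L, nstart = 100) {
  stopifnot(inherits(network, "affinity_network"), k >= 2)
  W <- network$W
  n <- nrow(W)
  if (k > n) stop("k must be <= number of samples")
  if (max(graph_components(W)) > 1)
    warning("affinity network is disconnected; components will separate in the embedding")
  dvec <- rowSums(W)
  if (any(dvec <= 0)) stop("sample with zero total similarity")
  Dis <- 1 / sqrt(dvec)
  M <- t(W * Dis) * Dis            # D^{-1/2} W D^{-1/2}
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  U <- eg$vectors[, seq_len(k), drop = FALSE]  # top-k of M = bottom-k of L
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100)
  labels <- km$cluster
  names(labels) <- network$sample_ids
  labels
}

#' Estimate the number of clusters by the eigengap heuristic
#'
#' Returns the k in 2..k_max maximizing the gap between consecutive ascending
#' eigenvalues of the normalized Laplacian, \eqn{\lambda_{k+1}-\lambda_k}.
#' Ties break toward smaller k. If the winning gap is below `weak_floor` the
#' result carries attribute `weak = TRUE` (no clear cluster structure).
#'
#' @param network an [affinity_network()].
#' @param k_max largest k considered (2 <= k_max < n).
#' @param weak_floor gap size below which the selection is flagged weak.
#' @return integer k with attributes `gap` and `weak`.
#' @export
estimate_k_eigengap <- function(network, k_max = 10, weak_floor = 0.05) {
  stopifnot(inherits(network, "affinity_network"))
  W <- network$W
  n <- nrow(W)
  if (k_max < 2 || k_max >= n) stop("need 2 <= k_max < n")
  dvec <- rowSums(W)
  Dis <- 1 / sqrt(dvec)
  L <- diag(n) - t(W * Dis) * Dis
  lambda <- sort(eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  ks <- 2:k_max
  gaps <- lambda[ks + 1] - lambda[ks]
  # ties (within numerical noise of the max) break toward smaller k
  best <- ks[which(gaps >= max(gaps) - 1e-10)[1]]
  structure(as.integer(best), gap = max(gaps), weak = max(gaps) < weak_floor)
}
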