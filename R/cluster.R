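#' K-means with silhouette model selection
#'
#' For each candidate k, runs k-means with `replicates` random restarts
#' (best within-cluster sum of squares kept) and computes the mean silhouette
#' width; the k with the highest mean silhouette wins.
#'
#' @param X standardized samples x features matrix.
#' @param k_values candidate cluster counts (default 2:5).
#' @param replicates random restarts per k (default 500).
#' @param seed integer seed.
#' @param silhouette_metric distance used for the silhouette
#'   ("euclidean" default, or "cosine").
#' @return a `clustering_run` list: labels, k, mean_silhouette, method,
#'   plus per-k silhouettes in `silhouette_by_k`.
#' @export
kmeans_select_k <- function(X, k_values = 2:5, replicates = 500, seed = 1L,
                            silhouette_metric = c("euclidean", "cosine")) {
  silhouette_metric <- match.arg(silhouette_metric)
  X <- as.matrix(X)
  if (any(k_values < 2)) stop("k = 1 rejected: silhouette undefined")
  if (max(k_values) >= nrow(X)) stop("max k must be < number of samples")
  if (max(stats::dist(X)) <= 0) stop("degenerate input: all samples identical")
  d <- switch(silhouette_metric,
              euclidean = stats::dist(X),
              cosine = stats::as.dist(cosine_dist(X)))
  set.seed(seed)
  runs <- lapply(sort(k_values), function(k) {
    km <- stats::kmeans(X, centers = k, nstart = replicates, iter.max = 300)
    sil <- cluster::silhouette(km$cluster, d)
    list(k = k, labels = km$cluster, mean_silhouette = mean(sil[, "sil_width"]))
  })
  sil_by_k <- vapply(runs, `[[`, numeric(1), "mean_silhouette")
  best <- runs[[which.max(sil_by_k)]]
  labels <- best$labels
  names(labels) <- rownames(X)
  structure(list(labels = labels, k = best$k,
                 mean_silhouette = best$mean_silhouette,
                 method = "kmeans", metric = silhouette_metric,
                 silhouette_by_k = stats::setNames(sil_by_k,
                                                   sort(k_values))),
            class = "clustering_run")
}

# Pairwise cosine distances between rows: 1 - cosine similarity
cosine_dist <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero-norm sample row under cosine metric")
  S <- tcrossprod(X / nrm)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

# 1 - Spearman rank correlation between sample profiles
spearman_dist <- function(X) {
  if (any(apply(X, 1, stats::sd) == 0)) {
    bad <- rownames(X)[apply(X, 1, stats::sd) == 0]
    stop(sprintf("constant sample profile under correlation metric: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  D <- 1 - stats::cor(t(X), method = "spearman")
  diag(D) <- 0
  D
}

#' Agglomerative hierarchical clustering of sample profiles
#'
#' @param X samples x features matrix.
#' @param metric "cosine", "spearman" (1 - rank correlation) or "euclidean".
#' @param linkage agglomeration method (default "complete").
#' @param k number of clusters to cut the tree into.
#' @return a `clustering_run` with the tree in `$hclust`.
#' @export
hierarchical_cluster <- function(X, metric = c("cosine", "spearman", "euclidean"),
                                 linkage = "complete", k = 2) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  D <- switch(metric,
              euclidean = stats::dist(X),
              cosine = stats::as.dist(cosine_dist(X)),
              spearman = stats::as.dist(spearman_dist(X)))
  hc <- stats::hclust(D, method = linkage)
  labels <- stats::cutree(hc, k = k)
  names(labels) <- rownames(X)
  sil <- if (k >= 2 && k < nrow(X))
    mean(cluster::silhouette(labels, D)[, "sil_width"]) else NA_real_
  structure(list(labels = labels, k = k, mean_silhouette = sil,
                 method = "hierarchical", metric = metric, linkage = linkage,
                 hclust = hc),
            class = "clustering_run")
}

#' @export
print.clustering_run <- function(x, ...) {
  cat(sprintf("<clustering_run: %s, k = %d, mean silhouette = %.3f>\n",
              x$method, x$k, x$mean_silhouette))
  invisible(x)
}

#' Rank features by Shannon entropy across samples
#'
#' Per feature, the entropy (in bits) of its histogram across samples using
#' `n_bins` equal-width bins over that feature's own observed range. High
#' entropy marks features whose values spread across the cohort; constant
#' features have entropy 0 and rank last. Ties break by feature id.
#'
#' @param X samples x features matrix with feature ids as colnames.
#' @param n_top number of features to return (e.g. 112 for a protein layer).
#' @param n_bins histogram bins (default 10).
#' @return character vector of the `n_top` highest-entropy feature ids, with
#'   the full entropy vector as attribute `entropy`.
#' @export
entropy_rank_features <- function(X, n_top, n_bins = 10) {
  X <- as.matrix(X)
  if (n_top > ncol(X)) stop("n_top exceeds number of features")
  ent <- apply(X, 2, function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(0)
    counts <- tabulate(
      pmin(n_bins, floor((x - rng[1]) / diff(rng) * n_bins) + 1L), n_bins)
    p <- counts[counts > 0] / length(x)
    -sum(p * log2(p))
  })
  ord <- order(-ent, colnames(X))
  structure(colnames(X)[ord][seq_len(n_top)], entropy = ent)
}

# Adjusted Rand index from the contingency table (Hubert & Arabie form)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)  # both partitions trivial and equal
  (sij - expected) / (max_index - expected)
}

# Best-match agreement: max fraction of samples agreeing under a label
# bijection; exact by enumeration over permutations of the smaller label set.
best_match_agreement <- function(a, b) {
  la <- sort(unique(a)); lb <- sort(unique(b))
  if (length(la) > length(lb)) return(best_match_agreement(b, a))
  if (length(lb) > 8) stop("best-match agreement supports up to 8 labels")
  tab <- table(factor(a, la), factor(b, lb))
  perms <- permutations_of(seq_along(lb))
  best <- 0
  for (p in perms) {
    hit <- sum(tab[cbind(seq_along(la), p[seq_along(la)])])
    if (hit > best) best <- hit
  }
  best / length(a)
}

permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

#' Concordance between two subtype assignments
#'
#' Adjusted Rand index plus the maximum fraction of samples that agree under
#' the optimal one-to-one label matching.
#'
#' @param a,b label vectors; if named, they are aligned by sample id.
#' @return list with `ari` and `agreement`.
#' @export
cluster_concordance <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0) stop("disjoint sample sets")
    if (length(common) < length(a) || length(common) < length(b))
      stop("sample sets differ; concordance requires the same samples")
    b <- b[names(a)]
  }
  if (length(a) != length(b)) stop("label vectors must have equal length")
  list(ari = adjusted_rand(a, b),
       agreement = best_match_agreement(a, b))
}
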