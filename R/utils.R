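#' Standardize a matrix column-wise
#'
#' Centers each feature to zero mean and scales to unit variance. Features
#' with zero variance are dropped with a warning (they carry no distance
#' information and would produce NaN after scaling).
#'
#' @param X numeric matrix, samples in rows.
#' @param center,scale optional numeric vectors of per-feature statistics to
#'   apply instead of computing them from `X` (used to standardize new data
#'   with training statistics).
#' @return standardized matrix with attributes `center` and `scale`.
#' @export
standardize_matrix <- function(X, center = NULL, scale = NULL) {
  X <- as.matrix(X)
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  zero_var <- scale <= .Machine$double.eps
  if (any(zero_var)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(zero_var),
                    paste(utils::head(colnames(X)[zero_var], 5), collapse = ", ")))
    X <- X[, !zero_var, drop = FALSE]
    center <- center[!zero_var]
    scale <- scale[!zero_var]
  }
  Z <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  Z
}

#' Mean-impute missing values column-wise
#'
#' @param X numeric matrix with possible NAs.
#' @return matrix without NAs; number of imputed cells reported via message.
#' @export
impute_missing <- function(X) {
  n_na <- sum(is.na(X))
  if (n_na > 0) {
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      if (any(miss)) X[miss, j] <- mean(X[, j], na.rm = TRUE)
    }
    message(sprintf("imputed %d missing value(s) by per-feature mean", n_na))
  }
  X
}

# Euclidean distance matrix on rows (dense, returns matrix not "dist")
row_dist <- function(X) {
  as.matrix(stats::dist(X, method = "euclidean"))
}

# Derive a stream-specific seed from a base seed; kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}
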