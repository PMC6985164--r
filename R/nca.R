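# Pairwise |x_ir - x_jr| design tensor, flattened column-major: row (j-1)*n+i
# of the output corresponds to matrix element [i, j].
nca_pair_design <- function(X) {
  n <- nrow(X); p <- ncol(X)
  A <- matrix(0, n * n, p)
  for (r in seq_len(p)) A[, r] <- c(abs(outer(X[, r], X[, r], "-")))
  A
}

# Soft leave-one-out neighbour probabilities for given nonnegative feature
# weights: p_ij = exp(-d_ij) / sum_{k != i} exp(-d_ik), d_ij = sum_r w_r |dx|,
# stabilized by the row-wise softmax shift.
nca_probs <- function(A, weights, n) {
  dmat <- matrix(A %*% weights, n, n)
  nd <- -dmat
  diag(nd) <- -Inf
  m <- apply(nd, 1, max)
  E <- exp(nd - m)
  E / rowSums(E)
}

#' Soft leave-one-out classification accuracy of an NCA weighting
#'
#' Evaluates \eqn{(1/n)\sum_i \sum_{j \neq i, y_j = y_i} p_{ij}} for a given
#' nonnegative per-feature weight vector, where the neighbour probabilities
#' use the weighted-L1 distance \eqn{d(i,j) = \sum_r w_r |x_{ir} - x_{jr}|}.
#' This is the data term of the NCA objective on the reported weight scale.
#'
#' @param X standardized samples x features matrix.
#' @param y class labels.
#' @param weights nonnegative per-feature weights.
#' @return scalar soft accuracy in [0, 1].
#' @export
nca_soft_accuracy <- function(X, y, weights) {
  X <- as.matrix(X)
  n <- nrow(X)
  P <- nca_probs(nca_pair_design(X), weights, n)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  mean(rowSums(P * same))
}

#' Fit diagonal NCA feature weights with regularisation
#'
#' Learns one nonnegative weight per feature by maximizing the regularised
#' soft leave-one-out nearest-neighbour accuracy
#' \deqn{F(w) = \frac1n \sum_i \sum_{j\neq i,\,y_j=y_i} p_{ij}
#'   \;-\; \lambda \sum_r w_r^2,}
#' with \eqn{p_{ij} \propto \exp(-d_w(i,j))} and the weighted-L1 distance
#' \eqn{d_w(i,j)=\sum_r w_r^2 |x_{ir}-x_{jr}|} (the diagonal adaptation: the
#' raw parameter is squared, so effective weights are nonnegative by
#' construction). Optimized by full-batch gradient ascent with halving
#' backtracking; the accepted-step objective trace is non-decreasing.
#'
#' @param X standardized samples x features matrix with feature ids.
#' @param y class labels (>= 2 classes, each with >= 2 members).
#' @param lambda regularisation strength >= 0 (default 1/n).
#' @param max_epochs maximum accepted gradient steps (default 200).
#' @param init_step initial step size (default 1).
#' @param tol stop when the relative objective gain falls below this.
#' @param layer_name label recorded on the panel.
#' @return a `biomarker_panel`: nonnegative `weights` (named, = squared raw
#'   parameters), `selected` (all features, by descending weight, until
#'   [select_panel()] is applied), `lambda`, `objective_trace`.
#' @export
fit_nca_weights <- function(X, y, lambda = NULL, max_epochs = 200,
                            init_step = 1, tol = 1e-8, layer_name = "layer") {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(p))
  y <- as.vector(y)
  if (length(unique(y)) < 2) stop("need at least 2 classes")
  if (min(table(y)) < 2) stop("every class needs at least 2 members")
  if (is.null(lambda)) lambda <- 1 / n
  if (lambda < 0) stop("lambda must be >= 0")

  A <- nca_pair_design(X)
  same <- outer(y, y, "==")
  diag(same) <- FALSE
  same_vec <- c(same)

  objective <- function(w) {
    P <- nca_probs(A, w^2, n)
    mean(rowSums(P * same)) - lambda * sum(w^4)
  }
  # gradient wrt raw parameter w (effective weight w^2):
  # dF/dw_r = (2 w_r / n) sum_{i,k} (p_i p_ik - same_ik p_ik) A_r(i,k)
  #           - 4 lambda w_r^3
  gradient <- function(w) {
    P <- nca_probs(A, w^2, n)
    pi_same <- rowSums(P * same)
    C <- P * pi_same - P * same
    as.vector((2 * w / n) * crossprod(A, c(C))) - 4 * lambda * w^3
  }

  w <- rep(1 / sqrt(sqrt(p)), p)   # effective weights w^2 = 1/sqrt(p) each
  f <- objective(w)
  trace <- f
  step <- init_step
  for (epoch in seq_len(max_epochs)) {
    g <- gradient(w)
    accepted <- FALSE
    for (try in 1:30) {
      w_new <- w + step * g
      f_new <- objective(w_new)
      if (is.finite(f_new) && f_new >= f) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted) break
    gain <- f_new - f
    w <- w_new; f <- f_new
    trace <- c(trace, f)
    step <- step * 1.2
    if (gain < tol * max(abs(f), 1)) break
  }

  weights <- w^2
  names(weights) <- colnames(X)
  structure(list(layer_name = layer_name,
                 weights = weights,
                 selected = names(sort(weights, decreasing = TRUE)),
                 lambda = lambda,
                 objective_trace = trace),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel '%s': %d features, %d selected, lambda = %.4g>\n",
              x$layer_name, length(x$weights), length(x$selected), x$lambda))
  invisible(x)
}

#' Select a biomarker panel from fitted NCA weights
#'
#' @param panel a `biomarker_panel` from [fit_nca_weights()].
#' @param rule "weight_threshold" (default; keep weights above
#'   `threshold_frac * max(weights)`) or "top_n" (fixed panel size, e.g. the
#'   50/49/14/20 panels).
#' @param n panel size for "top_n".
#' @param threshold_frac fraction of the maximum weight for
#'   "weight_threshold" (default 0.02).
#' @return the panel with `selected` replaced by the chosen features,
#'   ordered by descending weight.
#' @export
select_panel <- function(panel, rule = c("weight_threshold", "top_n"),
                         n = NULL, threshold_frac = 0.02) {
  rule <- match.arg(rule)
  w <- sort(panel$weights, decreasing = TRUE)
  sel <- switch(rule,
    top_n = {
      if (is.null(n) || n < 1 || n > length(w)) stop("need 1 <= n <= p for top_n")
      names(w)[seq_len(n)]
    },
    weight_threshold = {
      if (threshold_frac < 0) stop("threshold must be >= 0")
      if (max(w) <= 0) character(0)
      else names(w)[w >= threshold_frac * max(w)]
    })
  if (length(sel) == 0)
    stop("empty selection: lower the threshold or use top_n")
  panel$selected <- sel
  panel
}

#' Search for the smallest panel with minimal cross-validation loss
#'
#' For each candidate size s, takes the top-s NCA-weighted features and
#' estimates the stratified 5-fold CV loss of the supplied classifier;
#' returns the size with minimal loss (ties break toward the smaller panel).
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param sizes candidate panel sizes (default 3:10).
#' @param spec a [classifier_spec()] evaluated at each size.
#' @param folds CV folds (default 5).
#' @param seed integer seed (CV fold assignment).
#' @param lambda NCA regularisation (default 1/n).
#' @return list with `best_size`, `panel` (selected at the best size),
#'   `cv_loss` (named vector over sizes).
#' @export
minimal_panel_search <- function(X, y, sizes = 3:10, spec = classifier_spec("knn"),
                                 folds = 5, seed = 1L, lambda = NULL) {
  X <- as.matrix(X)
  if (max(sizes) > ncol(X)) stop("max panel size exceeds feature count")
  fit <- fit_nca_weights(X, y, lambda = lambda)
  ranked <- names(sort(fit$weights, decreasing = TRUE))
  losses <- vapply(sort(sizes), function(s) {
    keep <- ranked[seq_len(s)]
    1 - cross_validate(spec, X[, keep, drop = FALSE], y,
                       folds = folds, seed = seed)$accuracy
  }, numeric(1))
  names(losses) <- sort(sizes)
  best_size <- sort(sizes)[which.min(losses)]  # first minimum -> smallest s
  list(best_size = as.integer(best_size),
       panel = select_panel(fit, "top_n", n = best_size),
       cv_loss = losses)
}
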