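#' Specify a subtype classifier
#'
#' Families mirror the models used on the biomarker panels: k-nearest
#' neighbours (with a configurable Minkowski distance exponent, so exponent 3
#' gives the "cubic" KNN), support vector machines with a quadratic
#' (degree-2 polynomial) or Gaussian kernel, and bagged trees.
#'
#' @param family "knn", "svm" or "bagged_trees".
#' @param n_neighbors KNN neighbour count (>= 1).
#' @param distance_exponent Minkowski exponent for KNN (3 = cubic).
#' @param vote_weighting "uniform" or "distance" (inverse-distance votes).
#' @param kernel SVM kernel: "quadratic" or "gaussian".
#' @param cost SVM box constraint (> 0).
#' @param gamma SVM kernel scale (NULL = 1/p).
#' @param ntree number of bagged trees.
#' @param standardize fit-time standardization flag (statistics always come
#'   from the training data only).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = c("knn", "svm", "bagged_trees"),
                            n_neighbors = 5, distance_exponent = 3,
                            vote_weighting = c("uniform", "distance"),
                            kernel = c("quadratic", "gaussian"),
                            cost = 1, gamma = NULL, ntree = 200,
                            standardize = TRUE) {
  family <- match.arg(family)
  vote_weighting <- match.arg(vote_weighting)
  kernel <- match.arg(kernel)
  stopifnot(n_neighbors >= 1, cost > 0, distance_exponent > 0)
  structure(list(family = family,
                 n_neighbors = as.integer(n_neighbors),
                 distance_exponent = distance_exponent,
                 vote_weighting = vote_weighting,
                 kernel = kernel, cost = cost, gamma = gamma,
                 ntree = as.integer(ntree),
                 standardize = standardize),
            class = "classifier_spec")
}

# Minkowski distances from each row of Q to each row of R (Q x R matrix)
minkowski_dist <- function(Q, R, p) {
  t(apply(Q, 1, function(q)
    colSums(abs(t(R) - q)^p)^(1 / p)))
}

#' Train a subtype classifier
#'
#' @param spec a [classifier_spec()].
#' @param X training samples x features matrix (feature ids as colnames).
#' @param y class labels.
#' @param seed seed for stochastic fitters (SVM probability calibration,
#'   tree bagging).
#' @return a `trained_classifier` carrying the spec, the fitted state, the
#'   training standardization statistics and the class levels.
#' @export
train_classifier <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least 2 classes")
  if (spec$standardize) {
    Z <- standardize_matrix(X)
    center <- attr(Z, "center"); scale <- attr(Z, "scale")
  } else {
    Z <- X; center <- NULL; scale <- NULL
  }
  set.seed(seed)
  fit <- switch(spec$family,
    knn = list(Z = Z, y = y),
    svm = e1071::svm(Z, y, probability = TRUE, scale = FALSE,
                     kernel = if (spec$kernel == "quadratic") "polynomial" else "radial",
                     degree = 2, coef0 = 1, cost = spec$cost,
                     gamma = if (is.null(spec$gamma)) 1 / ncol(Z) else spec$gamma),
    bagged_trees = randomForest::randomForest(Z, y, mtry = ncol(Z),
                                              ntree = spec$ntree))
  structure(list(spec = spec, fit = fit,
                 feature_ids = colnames(X),
                 center = center, scale = scale,
                 classes = levels(y),
                 train_ids = rownames(X),
                 X_raw = X, y = y),
            class = "trained_classifier")
}

knn_posteriors <- function(model, Znew) {
  spec <- model$spec
  d <- minkowski_dist(Znew, model$fit$Z, spec$distance_exponent)
  classes <- model$classes
  post <- matrix(0, nrow(Znew), length(classes),
                 dimnames = list(rownames(Znew), classes))
  for (i in seq_len(nrow(Znew))) {
    ord <- order(d[i, ])[seq_len(min(spec$n_neighbors, ncol(d)))]
    w <- if (spec$vote_weighting == "distance")
      1 / (d[i, ord] + 1e-12) else rep(1, length(ord))
    votes <- tapply(w, factor(model$fit$y[ord], classes), sum, default = 0)
    post[i, ] <- votes / sum(votes)
  }
  post
}

#' Predict subtypes with a trained classifier
#'
#' Posterior class probabilities come from neighbour vote fractions (KNN),
#' sigmoid-calibrated decision values (SVM) or the out-of-vote fractions of
#' the tree ensemble. A prediction whose maximum posterior is below 0.7 is
#' flagged low-confidence.
#'
#' @param model a `trained_classifier`.
#' @param X_new new samples x features matrix; features are matched to the
#'   training features by id.
#' @param standardized set TRUE if `X_new` is already on the training scale
#'   (or externally standard-normalized, as in cohort transfer); otherwise
#'   the training statistics are applied.
#' @return data.frame with sample_id, label, per-class posterior columns and
#'   `low_confidence`.
#' @export
predict_classifier <- function(model, X_new, standardized = FALSE) {
  X_new <- as.matrix(X_new)
  missing <- setdiff(model$feature_ids, colnames(X_new))
  if (length(missing) > 0)
    stop(sprintf("missing %d training feature(s) in new data: %s",
                 length(missing), paste(utils::head(missing, 5), collapse = ", ")))
  X_new <- X_new[, model$feature_ids, drop = FALSE]
  Z <- if (!standardized && !is.null(model$center))
    standardize_matrix(X_new, center = model$center, scale = model$scale)
  else X_new
  post <- switch(model$spec$family,
    knn = knn_posteriors(model, Z),
    svm = {
      pr <- stats::predict(model$fit, Z, probability = TRUE)
      attr(pr, "probabilities")[, model$classes, drop = FALSE]
    },
    bagged_trees = stats::predict(model$fit, Z, type = "prob")[, model$classes,
                                                               drop = FALSE])
  stopifnot(all(abs(rowSums(post) - 1) < 1e-9))
  label <- model$classes[max.col(post, ties.method = "first")]
  out <- data.frame(sample_id = if (!is.null(rownames(X_new))) rownames(X_new)
                    else sprintf("Q%03d", seq_len(nrow(X_new))),
                    label = label, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(post))
  out$low_confidence <- apply(post, 1, max) < 0.7
  out
}

# stratified fold assignment: shuffles within class, deals folds round-robin
stratified_folds <- function(y, folds, seed) {
  if (min(table(y)) < folds)
    stop(sprintf("a class has fewer than %d members; use fewer folds", folds))
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Standardization (and SVM probability calibration) are fit inside each
#' training fold only; the held-out fold never influences preprocessing.
#'
#' @param spec a [classifier_spec()].
#' @param X samples x features matrix.
#' @param y class labels (each class needs >= `folds` members).
#' @param folds number of folds (default 5).
#' @param seed integer seed (fold assignment and stochastic fitters).
#' @return list with `accuracy`, `auroc` (2-class problems, else NA),
#'   `fold_accuracy` and the out-of-fold `predictions`.
#' @export
cross_validate <- function(spec, X, y, folds = 5, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%04d", seq_len(ncol(X)))
  if (is.null(rownames(X))) rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  y <- factor(y)
  fold <- stratified_folds(y, folds, seed)
  pred <- character(length(y))
  post2 <- numeric(length(y))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- train_classifier(spec, X[tr, , drop = FALSE], y[tr],
                              seed = derive_seed(seed, f))
    pr <- predict_classifier(model, X[!tr, , drop = FALSE])
    pred[!tr] <- pr$label
    if (nlevels(y) == 2) post2[!tr] <- pr[[model$classes[2]]]
    fold_acc[f] <- mean(pr$label == as.character(y[!tr]))
  }
  auroc <- if (nlevels(y) == 2)
    as.numeric(pROC::roc(y, post2, quiet = TRUE,
                         levels = levels(y), direction = "<")$auc)
  else NA_real_
  list(accuracy = mean(pred == as.character(y)),
       auroc = auroc,
       fold_accuracy = fold_acc,
       predictions = stats::setNames(pred, rownames(X)))
}

# one random draw from a family's hyperparameter space
sample_spec <- function(family, n, p) {
  switch(family,
    knn = classifier_spec("knn",
      n_neighbors = sample(seq_len(min(20, n - 2)), 1),
      distance_exponent = sample(c(1, 2, 3), 1),
      vote_weighting = sample(c("uniform", "distance"), 1)),
    svm = classifier_spec("svm",
      kernel = sample(c("quadratic", "gaussian"), 1),
      cost = 10^stats::runif(1, -2, 2),
      gamma = 10^stats::runif(1, -3, 1)),
    bagged_trees = classifier_spec("bagged_trees",
      ntree = sample(c(100, 200, 400), 1)))
}

#' Tune hyperparameters by minimizing cross-validation loss
#'
#' Random search over the family's hyperparameter space (log-uniform for
#' scale-like parameters), scoring each candidate by stratified 5-fold CV
#' loss. Any search strategy minimizing the same loss satisfies the same
#' contract; random search keeps the dependency surface small.
#'
#' @param family classifier family to tune.
#' @param X,y training data.
#' @param budget number of candidate specs evaluated (default 60).
#' @param folds CV folds.
#' @param seed integer seed.
#' @return the best [classifier_spec()] with attributes `cv_loss` (its loss)
#'   and `evaluated` (losses of all candidates).
#' @export
tune_hyperparameters <- function(family, X, y, budget = 60, folds = 5,
                                 seed = 1L) {
  if (budget < 1) stop("budget must be >= 1")
  set.seed(seed)
  candidates <- lapply(seq_len(budget), function(i)
    sample_spec(family, nrow(X), ncol(X)))
  losses <- vapply(seq_along(candidates), function(i)
    1 - cross_validate(candidates[[i]], X, y, folds = folds,
                       seed = derive_seed(seed, 1000 + i))$accuracy,
    numeric(1))
  best <- candidates[[which.min(losses)]]
  attr(best, "cv_loss") <- min(losses)
  attr(best, "evaluated") <- losses
  best
}

#' Transfer a trained panel classifier to an external cohort
#'
#' Intersects the biomarker panel with the external layer's features
#' (missing panel features are dropped from both the model and the data,
#' with a message); refits the model on the common features if any were
#' dropped; standard-normalizes the external biomarker matrix and predicts;
#' also clusters the same matrix (hierarchical, cosine, complete linkage)
#' and reports the best-match agreement between the supervised and
#' unsupervised labelings.
#'
#' @param model a `trained_classifier` fitted on panel features.
#' @param external_layer an [omics_layer()] for the external cohort.
#' @param panel a `biomarker_panel` (its `selected` features are used).
#' @param min_frac minimum fraction of panel features that must be present
#'   (default 0.5).
#' @return list with `predictions`, `clustering`, `agreement`,
#'   `features_used`.
#' @export
cohort_transfer <- function(model, external_layer, panel, min_frac = 0.5) {
  stopifnot(inherits(external_layer, "omics_layer"))
  sel <- panel$selected
  present <- intersect(sel, external_layer$feature_ids)
  if (length(present) < min_frac * length(sel))
    stop(sprintf("only %d of %d panel features present (< %.0f%%)",
                 length(present), length(sel), 100 * min_frac))
  if (length(present) < length(sel)) {
    message(sprintf("%d of %d panel features present; refitting model on the intersection",
                    length(present), length(sel)))
    model <- train_classifier(model$spec,
                              model$X_raw[, present, drop = FALSE], model$y)
  }
  Xe <- external_layer$values[, present, drop = FALSE]
  Ze <- standardize_matrix(impute_missing(Xe))
  pred <- predict_classifier(model, Ze, standardized = TRUE)
  hc <- hierarchical_cluster(Ze, metric = "cosine", linkage = "complete",
                             k = length(model$classes))
  supervised <- stats::setNames(pred$label, pred$sample_id)
  agr <- best_match_agreement(supervised, hc$labels[pred$sample_id])
  list(predictions = pred, clustering = hc, agreement = agr,
       features_used = present)
}
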