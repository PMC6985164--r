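blob_xy <- function(n = 40, p = 6, shift = 4, seed = 1) {
  set.seed(seed)
  y <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * p), n, p) + shift * (y - 1.5)
  rownames(X) <- sprintf("S%03d", 1:n)
  colnames(X) <- sprintf("f%02d", 1:p)
  list(X = X, y = y)
}

test_that("cross-validation is stratified, accurate on separable blobs, and seeded", {
  d <- blob_xy(shift = 5)
  spec <- classifier_spec("knn", n_neighbors = 3)
  cv <- cross_validate(spec, d$X, d$y, folds = 5, seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$auroc, 1)
  expect_identical(cross_validate(spec, d$X, d$y, folds = 5, seed = 1)$predictions,
                   cv$predictions)
  # class smaller than fold count is a clear error
  y_rare <- c(rep(1, 37), rep(2, 3))
  expect_error(cross_validate(spec, d$X, y_rare, folds = 5), "fewer")
})

test_that("label shuffling drops CV accuracy to chance (no leakage)", {
  d <- blob_xy(n = 60, shift = 5, seed = 2)
  set.seed(3)
  y_shuf <- sample(d$y)
  for (fam in c("knn", "svm")) {
    spec <- classifier_spec(fam, n_neighbors = 5)
    acc <- cross_validate(spec, d$X, y_shuf, folds = 5, seed = 4)$accuracy
    # 3 sd of binomial noise around 0.5 at n = 60
    expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 60) + 1e-9)
  }
})

test_that("KNN posteriors are vote fractions with the 0.7 confidence flag", {
  # training point predicted by its own 1-NN model: posterior 1, own label
  d <- blob_xy(n = 20, shift = 4, seed = 5)
  m1 <- train_classifier(classifier_spec("knn", n_neighbors = 1), d$X, d$y)
  pr <- predict_classifier(m1, d$X)
  expect_identical(pr$label, as.character(d$y))
  expect_true(all(apply(pr[, c("1", "2")], 1, max) == 1))
  expect_false(any(pr$low_confidence))
  # query equidistant from one neighbour of each class, k = 2, uniform votes
  Xt <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "f1"))
  m2 <- train_classifier(classifier_spec("knn", n_neighbors = 2,
                                         standardize = FALSE),
                         Xt, c(1, 2))
  q <- matrix(0, 1, 1, dimnames = list("Q", "f1"))
  pq <- predict_classifier(m2, q)
  expect_equal(unname(unlist(pq[, c("1", "2")])), c(0.5, 0.5))
  expect_true(pq$low_confidence)
  # posteriors sum to one for all families
  for (fam in c("svm", "bagged_trees")) {
    m <- train_classifier(classifier_spec(fam), d$X, d$y, seed = 1)
    pp <- predict_classifier(m, d$X)
    expect_equal(rowSums(pp[, c("1", "2")]), rep(1, 20), ignore_attr = TRUE,
                 tolerance = 1e-9)
  }
})

test_that("feature-id mismatches are reported by name", {
  d <- blob_xy(n = 20, seed = 6)
  m <- train_classifier(classifier_spec("knn"), d$X, d$y)
  X_bad <- d$X[, 1:4]
  expect_error(predict_classifier(m, X_bad), "f05")
})

test_that("hyperparameter tuning never returns worse than its own best candidate", {
  d <- blob_xy(n = 40, p = 4, shift = 1.2, seed = 7)
  tuned <- tune_hyperparameters("knn", d$X, d$y, budget = 12, seed = 2)
  expect_s3_class(tuned, "classifier_spec")
  expect_equal(attr(tuned, "cv_loss"), min(attr(tuned, "evaluated")))
  expect_length(attr(tuned, "evaluated"), 12)
  # budget 1 returns the single sampled spec
  one <- tune_hyperparameters("knn", d$X, d$y, budget = 1, seed = 3)
  expect_length(attr(one, "evaluated"), 1)
})

test_that("held-out cohorts from the generator are classified accurately", {
  ds <- generate_multiomics(standard_scenario(seed = 21))
  Z <- standardize_matrix(ds$layers$mRNA$values)
  pan <- select_panel(fit_nca_weights(Z, ds$true_labels, layer_name = "mRNA"),
                      "top_n", n = 50)
  model <- train_classifier(classifier_spec("knn", n_neighbors = 5,
                                            distance_exponent = 3),
                            ds$layers$mRNA$values[, pan$selected],
                            ds$true_labels)
  ext <- generate_multiomics(standard_scenario(seed = 22))
  pr <- predict_classifier(model, ext$layers$mRNA$values[, pan$selected])
  acc <- cluster_concordance(stats::setNames(as.integer(pr$label), pr$sample_id),
                             ext$true_labels)$agreement
  expect_gte(acc, 0.9)
})

test_that("cohort transfer drops missing panel features and self-transfer is consistent", {
  ds <- generate_multiomics(standard_scenario(seed = 23))
  Z <- standardize_matrix(ds$layers$mRNA$values)
  pan <- select_panel(fit_nca_weights(Z, ds$true_labels, layer_name = "mRNA"),
                      "top_n", n = 50)
  model <- train_classifier(classifier_spec("knn", n_neighbors = 5,
                                            distance_exponent = 3),
                            ds$layers$mRNA$values[, pan$selected],
                            ds$true_labels)
  # external cohort missing 5 of 50 panel features: refit on 45, logged
  ext <- generate_multiomics(standard_scenario(seed = 24))
  keep <- setdiff(ext$layers$mRNA$feature_ids, pan$selected[1:5])
  ext_layer <- omics_layer(ext$layers$mRNA$values[, keep], "mRNA")
  expect_message(res <- cohort_transfer(model, ext_layer, pan),
                 "45 of 50")
  expect_length(res$features_used, 45)
  expect_gte(res$agreement, 0.9)
  # fewer than half the panel present is an error
  tiny <- omics_layer(ext$layers$mRNA$values[, pan$selected[1:10]], "mRNA")
  expect_error(cohort_transfer(model, tiny, pan), "50%")
})
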