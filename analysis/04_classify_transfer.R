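#!/usr/bin/env Rscript
# Stage 4: supervised subtype classifiers on the biomarker panels — cubic
# KNN for mRNA, quadratic SVM for methylation — with stratified 5-fold CV,
# random-search hyperparameter tuning, and transfer of the mRNA model to an
# independent synthetic cohort (the ICGC-style validation).

suppressPackageStartupMessages(library(fuseomics))
SEED <- 1
datadir <- "results/data"
stopifnot(file.exists("results/panel_mRNA.tsv"))  # run 03 first

assign_df <- utils::read.delim("results/fused_assignments.tsv")
labels <- stats::setNames(assign_df$subtype, assign_df$sample_id)

get_panel <- function(nm) {
  tab <- utils::read.delim(sprintf("results/panel_%s.tsv", nm))
  tab$feature_id[tab$selected]
}

mrna <- read_layer_tsv(file.path(datadir, "mRNA.tsv"), "mRNA")
meth <- read_layer_tsv(file.path(datadir, "methylation.tsv"), "methylation")

specs <- list(
  mRNA = classifier_spec("knn", n_neighbors = 5, distance_exponent = 3),
  methylation = classifier_spec("svm", kernel = "quadratic"))
layers <- list(mRNA = mrna, methylation = meth)
cvres <- list()
for (nm in names(specs)) {
  Xp <- layers[[nm]]$values[, get_panel(nm)]
  cvres[[nm]] <- cross_validate(specs[[nm]], Xp, labels[rownames(Xp)],
                                folds = 5, seed = SEED)
  cat(sprintf("%-12s %s: 5-fold CV accuracy %.1f%%, AUROC %.3f\n",
              nm, specs[[nm]]$family, 100 * cvres[[nm]]$accuracy,
              cvres[[nm]]$auroc))
}

tuned <- tune_hyperparameters("knn", mrna$values[, get_panel("mRNA")],
                              labels, budget = 20, seed = SEED)
cat(sprintf("tuned KNN: k = %d, exponent %g, CV loss %.3f\n",
            tuned$n_neighbors, tuned$distance_exponent, attr(tuned, "cv_loss")))

# transfer to an independent cohort drawn with a new seed
panel_tab <- utils::read.delim("results/panel_mRNA.tsv")
panel <- structure(list(layer_name = "mRNA",
                        weights = stats::setNames(panel_tab$weight,
                                                  panel_tab$feature_id),
                        selected = panel_tab$feature_id[panel_tab$selected],
                        lambda = NA, objective_trace = NULL),
                   class = "biomarker_panel")
model <- train_classifier(specs$mRNA, mrna$values[, panel$selected], labels,
                          seed = SEED)
ext <- generate_multiomics(standard_scenario(seed = 2025))
res <- cohort_transfer(model, ext$layers$mRNA, panel)
acc <- cluster_concordance(
  stats::setNames(as.integer(res$predictions$label), res$predictions$sample_id),
  ext$true_labels)$agreement
cat(sprintf("transfer: supervised vs unsupervised agreement %.1f%%, accuracy vs truth %.1f%%\n",
            100 * res$agreement, 100 * acc))
cat(sprintf("low-confidence predictions (posterior < 0.7): %d of %d\n",
            sum(res$predictions$low_confidence), nrow(res$predictions)))
utils::write.table(res$predictions, "results/transfer_predictions.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
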