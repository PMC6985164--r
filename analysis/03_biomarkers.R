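#!/usr/bin/env Rscript
# Stage 3: biomarker panels per molecular layer by regularised diagonal
# neighbourhood component analysis against the fused-network subtypes,
# panel sizes mirroring the 50/49/14/20 convention, plus an
# entropy-based feature ranking of the protein layer.

suppressPackageStartupMessages(library(fuseomics))
datadir <- "results/data"
stopifnot(file.exists("results/fused_assignments.tsv"))  # run 02 first

assign_df <- utils::read.delim("results/fused_assignments.tsv")
labels <- stats::setNames(assign_df$subtype, assign_df$sample_id)

panel_sizes <- c(mRNA = 50, methylation = 49, protein = 14, miRNA = 20)
panels <- list()
for (nm in names(panel_sizes)) {
  layer <- read_layer_tsv(file.path(datadir, paste0(nm, ".tsv")), nm)
  Z <- standardize_matrix(layer$values)
  fit <- fit_nca_weights(Z, labels[rownames(Z)], layer_name = nm)
  panels[[nm]] <- select_panel(fit, "top_n", n = panel_sizes[nm])
  truth_inf <- readLines(file.path(datadir, paste0("informative_", nm, ".txt")))
  hits <- sum(panels[[nm]]$selected %in% truth_inf)
  cat(sprintf("%-12s panel of %2d: %2d/%2d are planted informative features\n",
              nm, panel_sizes[nm], hits, panel_sizes[nm]))
  utils::write.table(
    data.frame(feature_id = names(fit$weights), weight = unname(fit$weights),
               selected = names(fit$weights) %in% panels[[nm]]$selected),
    sprintf("results/panel_%s.tsv", nm),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

# entropy ranking of the protein layer (the 112-protein convention scaled to
# the 120-feature synthetic layer: top 24)
protein <- read_layer_tsv(file.path(datadir, "protein.tsv"), "protein")
top_entropy <- entropy_rank_features(protein$values, n_top = 24)
writeLines(top_entropy, "results/protein_entropy_top24.txt")
cat("entropy ranking of protein features written (top 24)\n")
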