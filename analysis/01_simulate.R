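#!/usr/bin/env Rscript
# Stage 1: generate the standard synthetic multi-omics cohort (45 samples,
# 2 planted subtypes, 4 layers; methylation/protein/miRNA carry 40%
# cross-platform discordance, mRNA is faithful) and write it as TSV.

suppressPackageStartupMessages(library(fuseomics))
SEED <- 1
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

ds <- generate_multiomics(standard_scenario(seed = SEED))
for (nm in names(ds$layers))
  write_layer_tsv(ds$layers[[nm]], file.path(outdir, paste0(nm, ".tsv")))
write_assignments_tsv(ds$true_labels, file.path(outdir, "truth.tsv"))
for (nm in names(ds$informative_features))
  writeLines(ds$informative_features[[nm]],
             file.path(outdir, paste0("informative_", nm, ".txt")))

cat(sprintf("cohort: %d samples, %d layers (%s)\n",
            length(ds$true_labels), length(ds$layers),
            paste(names(ds$layers), collapse = ", ")))
cat(sprintf("subtype sizes: %s\n",
            paste(table(ds$true_labels), collapse = " / ")))
for (nm in names(ds$discordant_samples))
  cat(sprintf("discordant samples in %s: %d\n", nm,
              length(ds$discordant_samples[[nm]])))
cat("written to", outdir, "\n")
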