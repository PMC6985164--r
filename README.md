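# fuseomics

Integrative tumour subtyping from multi-omics data, built as a reusable,
tested R pipeline. The scientific problem: single-platform clusterings of
the same tumours (mRNA, DNA methylation, protein/RPPA, miRNA) routinely
disagree, so subtype calls based on any one platform are unstable. The
package is aimed at computational biologists who want a desk-scale,
fully-reproducible implementation of the integrative workflow: similarity
network fusion, consensus clustering, biomarker selection, supervised
subtype classifiers, external-cohort transfer, and nearest-neighbour
drug-response prediction — validated end-to-end on synthetic cohorts with
known planted structure.

## The methods at the core

**Similarity network fusion (SNF).** Each layer yields a patient similarity
network from a locally scaled exponential kernel on standardized Euclidean
distances,

    W_ij = exp( − d_ij² / (α · ε_ij) ),   ε_ij = (μ_i + μ_j + d_ij) / 3,

with μ_i the mean distance from sample i to its K nearest neighbours
(defaults K = 24, α = 0.7). Layers are fused by iterative cross-diffusion of
row-stochastic status matrices through each layer's K-nearest-neighbour
graph, P_v ← S_v · mean(P_w, w≠v) · S_vᵀ, over t = 25 iterations. The fused
network is clustered by normalized-Laplacian spectral clustering with the
number of clusters chosen by the eigengap heuristic.

**Biomarker panels.** Regularised diagonal neighbourhood component analysis
(NCA): one nonnegative weight per feature, learned by maximizing the soft
leave-one-out nearest-neighbour accuracy minus λ·Σw², with a weighted-L1
sample distance. Panels are the top-weighted features (fixed size or
threshold), and a CV-loss scan finds minimal panels.

**Classifiers and transfer.** Cubic (Minkowski exponent 3) KNN and
quadratic-kernel SVM on the panels, stratified 5-fold CV with fold-internal
preprocessing, posteriors with a 0.7 low-confidence flag, and transfer to
external cohorts with panel intersection and agreement against unsupervised
clustering.

**Drug response.** An exhaustive squared-Euclidean nearest-neighbour
searcher over biomarker profiles; a line's predicted response per drug is
the categorized median of its neighbours' z-scored activity areas
(sensitive z > 0.8, resistant z < −0.8, otherwise intermediate), scored
against observed categories with the quadratic weighted Cohen's kappa.

**Statistics.** Welch t-tests with Benjamini–Hochberg correction,
hypergeometric over-representation, Kaplan–Meier curves with log-rank tests,
chi-square/Fisher association.

A synthetic-data module generates multi-omics cohorts with planted subtypes,
deliberate cross-platform discordance (so single layers fail but the fused
clustering recovers the truth), subtype-dependent drug panels and censored
survival — every downstream stage is tested against this ground truth. See
`vignettes/multiomics-subtyping.Rmd` for the models, parameter meanings and
design rationale.

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate.R` … `06_stats_survival.R`); each is a thin script over the
package functions and writes its tables under `results/`. Running stages 1,
2 and 5 prints:

```
$ Rscript analysis/01_simulate.R
cohort: 45 samples, 4 layers (mRNA, methylation, protein, miRNA)
subtype sizes: 23 / 22
discordant samples in methylation: 18
...

$ Rscript analysis/02_fuse_cluster.R
eigengap selects k = 2 (gap 0.097)
fused clustering vs truth: ARI 1.000, agreement 100.0%
  mRNA         single-layer spectral ARI 0.062
  methylation  single-layer spectral ARI 0.293
  protein      single-layer spectral ARI 0.293
  miRNA        single-layer spectral ARI 0.596
protein k-means: k = 2 chosen by silhouette (0.091)

$ Rscript analysis/05_drug_response.R
leave-one-out benchmark over 45 lines x 24 drugs: mean quadratic kappa 0.665
```

Reading: each platform alone clusters the cohort poorly (ARI 0.06–0.60
against the planted subtypes — the platforms were generated to disagree),
while the fused network recovers the truth exactly, and the eigengap
correctly identifies two subtypes. Leave-one-out drug-response prediction
from the 10 nearest expression neighbours reaches substantial ordinal
agreement (mean quadratic kappa ≈ 0.67). Stage 4 prints the panel
classifier's 5-fold CV accuracy and the agreement between supervised and
unsupervised subtype calls on an independent cohort; stage 6 prints the
differential-feature count, the enrichment of the planted informative set,
and subtype survival.

Alternatively `run_pipeline(pipeline_config(seed = 1))` executes all stages
into one output directory with checksums and resume support.

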