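---
title: "Integrative multi-omics subtyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative multi-omics subtyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseomics)
```

`fuseomics` implements an integrative tumour-subtyping workflow for cohorts
profiled on several molecular platforms (mRNA expression, DNA methylation,
protein/RPPA abundance, miRNA expression). Single-platform clusterings of the
same tumours routinely disagree; the workflow resolves this by fusing
per-platform patient similarity networks into one consensus network, clustering
that, and then carrying the consensus subtypes downstream: biomarker panels,
supervised classifiers, external-cohort transfer, drug-response prediction and
clinical statistics. This vignette explains each model, the parameters that
matter, and the design decisions taken where the design was genuinely open.

## Patient similarity networks and fusion

Each layer is a samples × features matrix. After per-feature mean imputation
of missing values (counts are messaged) and standardization to zero mean and
unit variance, the patient similarity for samples $i,j$ is a locally scaled
exponential kernel on the Euclidean distance $d_{ij}$:

$$W_{ij} = \exp\!\left(-\frac{d_{ij}^2}{\alpha\,\varepsilon_{ij}}\right),
\qquad
\varepsilon_{ij} = \frac{\mu_i + \mu_j + d_{ij}}{3},$$

where $\mu_i$ is the mean distance from $i$ to its $K$ nearest neighbours.
Local scaling makes the kernel self-tuning: dense and sparse neighbourhoods
get comparable similarity scales. Defaults are $K = 24$ neighbours and
$\alpha = 0.7$ ($\alpha$ in 0.3–0.8 is reasonable; smaller values sharpen the
network).

Fusion works on two row-stochastic views of each layer's network: the full
*status* matrix $P$ ($P_{ij} = W_{ij} / 2\sum_{k \ne i} W_{ik}$ off-diagonal,
$P_{ii} = 1/2$) and the *local* matrix $S$, which keeps only each sample's $K$
nearest neighbours (diagonal zero — neighbour sets exclude self; variants of
the method differ here, so it is fixed as part of the contract) and
renormalizes. Each iteration diffuses every layer's status matrix through its
own local graph using the other layers' consensus:

$$P_v \leftarrow S_v \,\bar P_{-v}\, S_v^{\top},$$

followed by symmetrization and status renormalization, for $t = 25$
iterations; the fused network is the symmetrized mean of the final status
matrices. Row-stochasticity is asserted at every iteration; the final
symmetrized average is near- but not exactly row-stochastic, and exact
symmetry is what the downstream spectral step requires. Local truncation is
what lets weak, noisy similarities be overridden by consistent evidence from
the other layers; identical input layers are a fixed point up to diffusion
smoothing, so the fused clustering then reproduces the single-layer one.

## Spectral clustering and model selection

The fused network is clustered by normalized spectral clustering: the top-$k$
eigenvectors of $L = I - D^{-1/2} W D^{-1/2}$, rows scaled to unit length,
then k-means with 100 restarts under a fixed seed (the determinism contract
holds because restarts are seeded and best-inertia selection is
deterministic). A disconnected network triggers a warning but no special
path: components separate exactly in the null eigenspace of $L$, so the
embedding already clusters them.

The number of clusters is chosen by the eigengap heuristic:
$\hat k = \arg\max_{k \in \{2..k_\text{max}\}} (\lambda_{k+1} - \lambda_k)$
over the ascending Laplacian eigenvalues. Ties (within $10^{-10}$, which also
absorbs numerical jitter on exactly tied spectra) break toward smaller $k$. A
winning gap below `weak_floor` (default 0.05 on eigenvalues that live in
$[0, 2]$) flags the selection as weak — a complete graph, for example,
returns $k = 2$ with a zero, flagged gap.

Single-platform baselines mirror common practice: k-means with 500 random
restarts per candidate $k \in \{2..5\}$ selected by mean silhouette ("500
iterations" is read as 500 restarts with the best within-cluster sum of
squares kept, per-run iteration cap 300, since restarts are what affect
solution quality; the silhouette metric defaults to Euclidean and is
configurable because the choice is not determined by the workflow), plus
agglomerative clustering with cosine, Spearman (1 − rank correlation) or
Euclidean distances and complete linkage. Partition agreement is quantified
by the adjusted Rand index and by best-match agreement (the maximum fraction
of samples agreeing under an optimal label bijection, found exactly by
enumeration for up to 8 labels).

## Biomarker selection: regularised diagonal NCA

Per layer, one nonnegative weight per feature is learned by maximizing the
soft leave-one-out nearest-neighbour classification accuracy

$$F(w) = \frac1n \sum_i \sum_{j \ne i,\, y_j = y_i} p_{ij}
 \;-\; \lambda \sum_r w_r^2,
\qquad
p_{ij} = \frac{\exp(-d_w(i,j))}{\sum_{k \ne i} \exp(-d_w(i,k))},$$

with the weighted-L1 (diagonal) distance $d_w(i,j) = \sum_r w_r
|x_{ir}-x_{jr}|$, where $w_r$ is the square of a raw unconstrained parameter
— nonnegativity by construction. The optimizer is full-batch gradient ascent
with halving backtracking (initial step 1, at most 200 accepted steps,
stop at relative gain $<10^{-8}$), so the accepted objective trace is
non-decreasing and the fit is deterministic. Raw parameters start at
$p^{-1/4}$ (effective weights $1/\sqrt p$), putting initial pairwise
distances on the scale of a mean absolute difference; softmax rows are
max-shifted so large distances cannot underflow. The default
$\lambda = 1/n$ is the standard choice for this formulation; it is exposed,
and `minimal_panel_search()` additionally scans panel sizes (default 3–10)
by stratified 5-fold CV loss, breaking ties toward the smaller panel.

Panels are cut from the ranked weights either by a threshold (default 2% of
the maximum weight) or by fixed size (`top_n`), the latter matching
fixed-size panel conventions such as 50 mRNAs / 49 methylated genes / 14
proteins / 20 miRNAs. Note that only `top_n` can reproduce exact published
panel sizes, since no threshold rule is implied by them.

## Classifiers, transfer and confidence

The classifier families are k-nearest neighbours with a configurable
Minkowski exponent (exponent 3 is the "cubic" KNN convention), SVM with a
quadratic (degree-2 polynomial) or Gaussian kernel, and bagged trees
(a random forest with `mtry` equal to the feature count). Cross-validation is
stratified 5-fold with preprocessing fit inside each training fold only —
the label-shuffle control in the test suite checks the no-leakage property.
Hyperparameter search minimizes 5-fold CV loss within a budget (default 60
random draws, log-uniform for scale-like parameters); any strategy
minimizing the same loss satisfies the same contract, and random search
keeps the dependency surface small.

Posteriors are neighbour vote fractions (KNN), sigmoid-calibrated decision
values (SVM, calibrated on training folds), or ensemble vote fractions
(bagged trees); a prediction whose maximum posterior is below 0.7 is flagged
low-confidence — the transfer-audit convention. Cohort transfer intersects
the panel with the external layer's features (at least half must be present),
refits on the intersection when features are missing, standard-normalizes
the external matrix by its own statistics (cross-platform scales are not
comparable, so training statistics are deliberately not reused), predicts,
and reports best-match agreement with an unsupervised hierarchical
clustering (cosine, complete linkage) of the same matrix.

## Drug-response prediction

Cell lines are embedded by their standard-normalized biomarker profiles in an
exhaustive nearest-neighbour searcher under squared Euclidean distance
(ties break by id order; brute force is exact at these scales, and the
rank-based `n = 10` neighbours is used rather than any fixed radius). Per
drug, activity areas are z-scored across lines and categorized with strict
boundaries: $z > 0.8$ sensitive, $z < -0.8$ resistant, otherwise
intermediate — the boundary values themselves are intermediate. A query
line's predicted response is the categorized *median* of its data-bearing
neighbours' z-scores (neighbours without drug data are skipped rather than
widening the search); with exactly two such neighbours the median equals
their mean, which reconciles the median rule with two-neighbour worked
examples. z-normalization is per drug (column-wise) because sensitivity
calls are only meaningful relative to other lines on the same drug.

Agreement between predicted and observed ordinal categories is the quadratic
weighted Cohen's kappa over the full $C \times C$ grid (unobserved categories
included; expected counts from marginal products). Two constant, identical
raters give $\kappa = 1$ by convention. The leave-one-out benchmark predicts
every data-bearing line from its neighbours and averages per-line kappas; a
single-drug table switches to one kappa pooled across lines, since a
per-line kappa over one drug is degenerate.

## Statistics

Differential abundance uses Welch's unequal-variance t-test per feature with
Benjamini–Hochberg correction (significance at $q < 0.05$). This is applied
to all layers' normalized values; a moderated count-model test is *not* used
for mRNA because the workflow operates on normalized continuous matrices
throughout. Zero-variance features get $p = 1$ with a flag rather than an
error. Overrepresentation uses the upper-tail hypergeometric test against an
explicit universe, BH-corrected across sets (a 10% FDR display threshold is
a configuration of the same test, not a separate method). Survival uses the
Kaplan–Meier product-limit estimator, median survival as the smallest time
with $S(t) \le 0.5$ ("not reached" reported as NA) and the log-rank test;
categorical association uses Pearson's chi-square without continuity
correction, plus Fisher's exact test for 2×2 tables.

## The synthetic-data generator: what it emulates, and what it does not

`generate_multiomics()` plants `n_subtypes` balanced subtypes in `n_samples`
samples and builds each layer as Gaussian noise in which the informative
features carry a between-subtype mean shift of `effect_size` noise standard
deviations. Informative features occupy the first columns before a seeded
column shuffle; their ids are recorded as ground truth.

Cross-platform discordance — the empirical phenomenon that different
platforms cluster the same tumours differently — is emulated by permuting the
informative-feature sub-rows of a fraction of samples within a layer. This
preserves every feature's marginal distribution exactly (unlike added noise)
while decoupling that layer's signal from the truth for those samples. The
scenario is defined by a recoverable consensus: single-layer clusterings
must fail while the fused clustering succeeds. Two design choices follow
from that definition:

* **Near-disjoint discordant sets.** At discordance 0.4 on three of four
  layers, $3 \times 0.4 n > n$, so fully disjoint discordant sets are
  impossible. Discordant samples are allocated preferentially to samples
  least used by earlier layers, and a sample drafted a *second* time has its
  block permuted within its own subtype — still reshuffled, but no longer
  contradicting the truth. Without this, roughly two samples per cohort are
  corrupted toward the wrong subtype in two layers and sit at an exact 2:2
  tie that no consensus method can break; with it, every sample retains a
  3:1 majority of truth-consistent layers.
* **Calibration.** Feature counts are 400/300/120/150 per layer with
  60/45/24/30 informative (15–20%), effect size 2, noise 1. This puts each
  single layer's clustering well below perfect (spectral ARI roughly 0.05–0.6
  across layers and seeds) while the fused network recovers the truth (ARI
  ≥ 0.9 in essentially all seeds) — the defining property of the scenario.
  With substantially sparser informative fractions the clean layers are
  individually too weak for any consensus to resolve the corrupted samples,
  which changes what is being tested from the method to the scenario.

The standard tumour scenario keeps mRNA as the faithful layer (methylation,
protein and miRNA carry the discordance), because the downstream classifier,
transfer and drug stages all ride on the mRNA biomarker panel — mirroring how
mRNA panels transfer across cohorts in practice. `cell_line_scenario()` is a
single clean mRNA layer: discordance models disagreement *between* platforms
of the same tumours and has no counterpart in a one-layer cell-line panel.

`generate_drug_panel()` gives each drug a random sensitive-subtype direction
and a per-drug between-subtype separation of `subtype_effect` times a uniform
multiplier on (1.5, 3.5). Drugs genuinely differ in how strongly they
discriminate molecular subtypes, and this heterogeneity matters: with one
fixed separation, two balanced subtypes pin every drug's z-means to ±0.71 —
inside the intermediate band — and the median-of-neighbours predictor
degenerates to always "intermediate". The chosen range spans drugs whose
discriminated subtype lies clearly beyond the ±0.8 boundary alongside drugs
near it, and reproduces the observed agreement regime (mean leave-one-out
quadratic kappa around 0.7 at the default effect 2, noise 1).

`generate_survival()` draws exponential event times with a per-subtype scale
(mean survival, months) and applies genuinely independent censoring: a
competing exponential censoring time whose rate is calibrated so the
expected censored fraction equals `censor_rate` within each subtype. The
Kaplan–Meier estimator therefore stays unbiased under censoring (the naive
alternative — censoring at a random fraction of the event time — biases
medians downward).

What the generator does *not* emulate: methylation bounded in [0, 1] (all
layers are Gaussian — a documented simplification), feature–feature
correlation structure, batch effects, heavy-tailed expression, unbalanced
subtypes, or missing-at-random patterns beyond what the imputation path
handles. Passing tests on this generator therefore demonstrate correctness
of the machinery and recoverability under the planted model, not performance
on real cohorts: the corresponding quantities on real data (CV accuracies,
transfer agreement, drug-response kappa) depend on cohort-scale
TCGA/ICGC/CCLE downloads that are not packaged.

## Numerical choices and degenerate inputs

* Zero-variance features are dropped with a warning before standardization;
  an all-constant layer is an error (zero kernel bandwidth).
* Identical samples get similarity exactly 1; an isolated sample (zero row
  sum) is an error naming the sample.
* Neighbour-search ties break by id order; eigengap ties toward smaller k;
  panel-size ties toward smaller panels; k-means ties resolved by seeded
  restarts and best inertia.
* The 0.7 posterior flag and the ±0.8 category boundaries are strict
  comparisons, honoured exactly at the boundary.
* Problem sizes used throughout the shipped analyses and tests — cohorts of
  45 samples, up to 2000 features in the selection benchmark, 20-seed
  recovery sweeps — were chosen as representative desk-scale versions of the
  study design.

## Known limitations

* The fused network's spectral labels depend on k-means restarts only through
  the seed; cross-platform reproducibility of eigenvector signs is handled by
  row normalization, but eigenvalue near-ties in weakly structured networks
  can still flip labels between R builds.
* NCA is non-convex; the deterministic optimizer finds a reproducible local
  optimum, not a certified global one. Duplicated features split weight
  between copies (the soft accuracy is invariant to such splits).
* Best-match agreement enumerates label bijections and is limited to 8
  labels; ARI has no such limit.
* The drug predictor assumes neighbours' drug data are missing completely at
  random; informative missingness would bias the median.
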