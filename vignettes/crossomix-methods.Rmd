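---
title: "Cross-platform toxicogenomics classification: models and methods"
author: "crossomix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform toxicogenomics classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossomix)
```

# The problem

Short-term rodent studies produce mRNA, miRNA and protein expression
profiles of liver tissue after treatment with chemical compounds. The
scientific question is whether those profiles, taken a few days after
exposure, predict the outcome of a two-year carcinogenicity bioassay —
specifically whether a compound behaves as a genotoxic carcinogen (GC), a
non-genotoxic carcinogen (NGC) or a non-hepatocarcinogen (NC). The package
implements a cross-platform approach: instead of classifying on one
platform's fold changes alone, it constructs features that integrate the
three molecular layers and evaluates them with a panel of classifiers under
compound-level cross-validation. Three binary contrasts are supported:
carcinogens (GC and NGC pooled) versus NC, NGC versus GC, and NGC versus
NC.

# Input model and preprocessing

All downstream computation operates on log2 fold changes of treated samples
against time-matched vehicle control groups. `compute_fold_changes()`
subtracts a per-feature control summary: the median for antibody-panel
protein data (whose normalisation convention divides by the control-group
median before log transformation), the mean for mRNA/miRNA intensities on
the RMA-style log2 scale. Both summaries are exposed through
`control_stat`, because the choice is a convention, not a law.

Protein panels come with two wrinkles handled in `preprocess`:

* **Background masking.** A measurement whose secondary-antibody-only
  background reaches the combined specific signal carries no information;
  `normalize_protein_panel()` masks it as missing rather than keeping a
  ratio of noise terms.
* **Imputation.** `knn_impute()` fills missing cells (around 1% of protein
  data in the emulated design) with the unweighted mean of the k = 5
  nearest features' values in the affected sample. Distances are
  root-mean-square Euclidean over co-observed samples, computed on
  row-standardised profiles so that high-amplitude features do not dominate
  neighbour selection. k = 5 is the customary default for expression
  matrices of this shape; both k and the standardisation are configurable
  choices, not estimates. Observed cells are never altered, and a feature
  sharing no observed samples with any other feature is an error rather
  than a guess.

Features never detected in any sample are removed by
`filter_unexpressed()`; detection in a single sample is enough to retain a
feature, because the removal rule targets probes that were dead everywhere.

# Molecular-interaction (MI) features

Platforms differ in dynamic range — a two-fold protein change and a
two-fold miRNA change are not comparable numbers. Each platform's
log-ratios are therefore mapped to a common interval by
`g(x) = x / m_max`, where `m_max` is the largest absolute log-ratio
observed on that platform's reference set, yielding values in [−1, 1].
For each putative cross-layer interaction the per-sample score is the
product of the two members' scaled log-ratios:

* miRNA → target mRNA, expected anti-correlated (score near −1),
* mRNA → protein of the same gene locus, expected co-regulated (near +1),
* miRNA → protein, transitively inferred through the targeted mRNA,
  expected anti-correlated.

Interaction candidates come from target tables (validated and predicted
evidence both enter MI features) and from gene-locus maps. Chains through
different mediating mRNAs remain distinct features, since their products
genuinely differ and collapsing them would require an aggregation rule with
no principled choice. Scores are computed unconditionally for machine
learning; the sign expectation is only enforced by
`highlight_interactions()`, the reporting filter that demands at least a
1.5-fold change in both partners plus sign concordance.

Two numerical choices deserve note. First, in cross-validation the scaling
context is fitted on training samples only and applied to held-out samples
with clipping to [−1, 1]; fitting on all samples would leak the test
fold's dynamic range into training. Second, an all-zero platform
(`m_max = 0`) maps to zero scores rather than dividing by zero.

# Pathway-enrichment (PE) features

Per sample, features with absolute linear fold change strictly above 2.5
count as deregulated. The threshold is interpreted on the linear scale
(|log2FC| > log2 2.5 ≈ 1.322) and strictly, reading "above" literally; it
is configurable. Deregulated mRNAs and proteins map to gene loci;
deregulated miRNAs — absent from canonical pathways — are represented by
the genes of their *experimentally validated* targets only, because
predicted targets would flood the gene list with noise at this step. The
union of these genes is tested against every pathway with the upper-tail
hypergeometric test. With a universe of N genes (the union of all loaded
pathway sets, pooled across databases), M of them in the pathway, n
deregulated genes inside the universe and m of those in the pathway:

$$p = \sum_{k=m}^{\min(n,M)} \frac{\binom{M}{k}\binom{N-M}{n-k}}{\binom{N}{n}}$$

evaluated in log space (`phyper(..., log.p = TRUE)`) so that −log10(p)
scores stay finite for extreme enrichments. Deregulated genes outside the
universe are excluded from n — counting them would violate the sampling
model — and their number is reported. No multiple-testing correction is
applied: the scores are classifier features, not inferences. The per-sample
score vector over all pathways, ordered by id with a source prefix
(K/R/B/C), forms the PE feature block.

# Signature inference

`svm_rfe()` implements recursive feature elimination with a linear
maximum-margin classifier: train, rank features by squared weight,
eliminate the worst `max(1, floor(0.1 × remaining))`, repeat; once at most
twice the target size remains, elimination proceeds one feature at a time.
The 10% schedule balances fidelity to one-at-a-time elimination against
runtime and is configurable. Features are standardised before ranking —
weight magnitudes are only comparable on a common scale — and ties within
a round break by weight magnitude, then feature id, making the ranking a
deterministic permutation of the input.

Candidate signature sizes {5, 10, 15, 20, 25} are scored by inner-fold
accuracy; a cubic interpolating spline through (size, accuracy) is
evaluated on every integer in the grid range and the argmax (ties toward
the smaller size) is the selected size. With fewer than three points the
grid argmax is used directly.

Rankings from all folds and repetitions merge into a consensus signature by
average rank; a feature unseen by one fold's ranking receives that
ranking's length + 1 — a pessimal rank — so that features must rank well
consistently, not once.

# Evaluation protocol

`make_split_plan()` draws repeated 2×2 nested, stratified splits at the
*compound* level: all replicates of a compound travel together, because
replicate animals of one compound are correlated and sample-level splits
would let the classifier recognise compounds rather than classes. Each
outer fold provides unseen test compounds of both classes; inner folds of
the training compounds tune hyperparameters and signature size. Per outer
fold, standardisation, zero-variance/incompleteness filtering, MI scaling,
RFE ranking and tuning all touch training samples only. Held-out scores
are scaled linearly to [0, 1] per fold (a degenerate all-equal fold maps
to 0.5) and merged across folds and repetitions into one ROC per
classifier; AUC is the Mann–Whitney statistic with ties counted one half.
Per-repetition AUCs are kept for dispersion. Classifier failures are
caught, warned about, and the fold is marked invalid rather than silently
imputed.

Five classifier backends ship by default: linear SVM (cost grid
0.01–10), random forest (500 trees, √p or p/3 variables per split),
single-hidden-layer neural network (3/5/10 units, decay 0.1/0.01),
Bayesian logistic regression implemented as the MAP estimate under a
weakly informative Gaussian coefficient prior (ridge-penalised, penalty
1/n), and principal-component logistic regression (1–10 components). The
grids are conventional defaults and configurable; hyperparameters are only
ever chosen on inner folds.

Compounds labelled UNDEFINED never enter training. `classify_undefined()`
trains on the confidently labelled compounds, restricts to a signature,
and reports per-classifier confidences in [0, 1] (raw scores scaled
against the training-score range) plus a compound-level majority call.
`pca_view()` (centred PCA, deterministic sign convention: the
largest-magnitude loading of each component is positive) and
`cluster_view()` (top-100 features per platform by mean |log2FC|,
complete-linkage Euclidean clustering, cluster count 2–8 chosen by mean
silhouette width) provide the unsupervised views.

# The synthetic generator

`generate_synthetic()` emulates the three-platform study design so every
stage is testable without external data. Defaults mirror the emulated
study: 2 GC, 8 NGC, 2 NC and 3 UNDEFINED compounds, 3 replicate animals
per compound, 2000 mRNA probes, 300 miRNAs, a 158-antibody protein panel,
and ~1% missing protein cells. Each cell is

```
log2FC = class effect (±δ for planted features) + compound effect + noise
```

with δ = 2 by default, a Gaussian compound-level random effect
(sd 0.25) shared by a compound's replicates — this is what makes
compound-level splits meaningful, replicates of one compound cluster — and
replicate noise of sd 0.5. Planted miRNAs take the opposite sign of their
target mRNA; planted proteins inherit their cognate mRNA's sign; one
pathway per class collects that class's planted mRNA genes. UNDEFINED
compounds reuse the NGC effect structure, matching the biological reading
that such compounds act through non-genotoxic mechanisms. Fold changes are
generated directly by default; the worked example and tests also exercise
the absolute-expression route through `compute_fold_changes()`.

What the generator does **not** emulate: probe-level microarray noise,
spatial artifacts, platform-specific detection limits, correlated nuisance
pathways, or dose–response structure. Passing tests on synthetic data
therefore demonstrate that the machinery recovers planted structure under
idealised noise, not that any particular real dataset will reach a given
AUC.

# Problem sizes and reproducibility

All randomness flows from explicit integer seeds; reruns with the same
seed are bit-identical, and classifier RNG (forest bootstraps, network
initialisation) is re-seeded per fold so that fold results do not depend
on evaluation order. The test suite and `scripts/acceptance.R` use the
study-sized generator (2000 mRNA features, 4 compounds per class) for
feature-recovery and null-control experiments, and a reduced evaluation
size (400 mRNA / 60 miRNA / 40 protein features) for the two-arrangement
comparison, which keeps a 10-repetition, five-classifier comparison
tractable on a single core while preserving the feature-to-sample regime
(features ≫ samples) that drives the statistics.

# Known limitations

* With 4 compounds per class, per-repetition null AUC estimates are
  heavily quantised: a merged ROC rests on 8 effectively independent
  compound units, so individual repetitions of a null experiment scatter
  widely around 0.5 (dispersion ≈ 0.13) even though the mean across
  repetitions sits at chance. Null-control conclusions should be drawn
  from the mean over repetitions, not from single repetitions.
* The per-fold [0, 1] score scaling makes scores comparable across folds
  but discards calibration; confidences from `classify_undefined()` are
  rankings dressed as probabilities, not calibrated posteriors.
* Probe sets mapping to several genes are expanded to all mapped genes by
  default (`multi = "expand"`); the alternative of dropping ambiguous
  probes is provided because neither convention is universally right.
* The hypergeometric tail is evaluated in log space; against direct
  combinatorial summation it agrees to about one unit in the last floating
  point place, which is visible only when comparing at tolerance 0.
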