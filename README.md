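# ibcsig

Discovery and validation of class-specific gene-expression signatures
with bagged classification-tree ensembles, built around the
inflammatory breast cancer (IBC) use case.

IBC is a rare, aggressive breast cancer subtype whose transcriptional
signatures have historically transferred poorly between cohorts.
`ibcsig` is for computational biologists who want to derive such a
signature from a labeled expression cohort and then stress-test it the
way a skeptical reviewer would: does it beat random gene sets of the
same size, does it survive transfer to an independent batch-shifted
cohort, does it separate samples without seeing the labels, and do the
predicted classes differ in survival?

## The method

Given a log2 expression matrix with class labels and ER/HER2 receptor
scores:

1. **Matched design** — positive and negative training samples are
   exact-matched on the ordinal `(ER, HER2)` score pair (maximum
   pairing per score stratum, deterministic tie-breaks), so the
   classifier cannot simply learn hormone-receptor subtype.
2. **Ensemble ranking** — a bagged ensemble of classification trees is
   trained on all genes; each gene gets an out-of-bag permutation
   importance (mean decrease in accuracy when that gene is permuted in
   the out-of-bag samples). The signature is the top *k* genes
   (default *k* = 59).
3. **Probability scoring** — a sample's score is the fraction of trees
   voting the positive class, *s* = votes⁺/`n_trees` ∈ {0, 1/T, …, 1};
   a sample is called positive iff *s* > 0.5 (strict).
4. **Specificity null** — ensembles retrained on uniformly random
   size-matched gene sets give a null distribution of holdout accuracy;
   the signature's empirical p-value is the add-one estimate
   *p* = (1 + #{a ≥ observed}) / (n + 1).
5. **Unsupervised corroboration** — hierarchical clustering with the
   Calinski–Harabasz index CH(k) = [B/(k−1)]/[W/(n−k)] to pick the
   cluster number, and sign-stabilized PCA.
6. **Context** — nearest-centroid intrinsic subtyping by Spearman
   correlation with a pluggable centroid panel plus a
   risk-of-recurrence score, and Kaplan–Meier / log-rank survival
   comparison of predicted classes with the Mantel–Haenszel hazard
   ratio HR = (O₁/E₁)/(O₂/E₂).

A synthetic-cohort simulator with a planted bidirectional signature,
receptor covariates, batch-shifted validation cohorts, post-treatment
attenuation and class-dependent hazards makes the whole pipeline
testable end to end. See the vignette
(`vignettes/signature-discovery.Rmd`) for the model details and design
choices.

## Worked example

```r
library(ibcsig)

cfg <- simulationConfig(seed = 1)          # 2000 genes, 20/20/5 samples,
sim <- simulateCohort(cfg)                 # 59 planted genes at 1.5 SD
sim$cohort
#> ExpressionCohort: 2000 genes x 45 samples
#>   classes: IBC:20, nonIBC:20, normal:5

design <- matchTrainingSet(sim$cohort, allow_unmatched = 1)
design
#> MatchedDesign: 19 matched pairs, 2 unmatched fill-ins; 40 training / 5 holdout samples

sig <- discoverSignature(sim$cohort, design, k = 59,
                         forestConfig(n_trees = 2000, seed = 7))
length(intersect(sigGenes(sig), sim$truth@planted_genes))
#> [1] 47        # 47/59 planted genes recovered

vpre <- simulateValidationCohort(cfg, sim$truth, "pre")   # 33 IBC / 28 nonIBC
val <- validateSignature(vpre, sig, trainingIds(design),
                         forestConfig(seed = 8), training_cohort = sim$cohort)
val$result
#> ClassificationResult: 61 samples; 33 called IBC (threshold > 0.5)
val$accuracy
#> [1] 1         # every batch-shifted validation sample classified correctly

hierCluster(sim$cohort, sig, k_max = 8)
#> ClusteringResult: 45 samples, k = 2..8 ; optimal k = 2

st <- simulateSurvival(classLabels(vpre), cfg)   # true hazard ratio 3.15
r <- logrankHr(st, reference = "other")
#> log-rank chisq = 13.30, p = 0.000266, HR = 2.45 (95% CI 1.35-4.43)
```

The discovered signature recovers most planted genes, transfers across
the batch shift, and the Calinski–Harabasz criterion independently
splits the cohort into the two planted groups; the survival comparison
recovers an elevated hazard for the positive class.

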