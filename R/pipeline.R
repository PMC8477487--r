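#' Discover a top-k gene signature by ensemble importance
#'
#' Trains a bagged-tree ensemble on all cohort genes over the matched
#' training set, ranks genes by importance, and returns the top
#' \code{k} unique genes with their scores. Deterministic for a fixed
#' config seed.
#'
#' The default ranking forest is larger (5000 trees) than the
#' classification default (500): with thousands of candidate genes and
#' \code{sqrt(p)} features per split, each gene competes in relatively
#' few splits per tree, and permutation-importance estimates — hence the
#' top-k cut — stabilize considerably more slowly than the ensemble's
#' predictions do.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param design a \linkS4class{MatchedDesign} (or any list with a
#'   \code{training_ids} element).
#' @param k signature size (default 59).
#' @param cfg a \linkS4class{ForestConfig}; defaults to
#'   \code{forestConfig(n_trees = 5000)}.
#' @param positive positive class label.
#' @param name signature name.
#' @return a \linkS4class{GeneSignature} whose provenance records the
#'   training set and key parameters.
#' @export
discoverSignature <- function(cohort, design, k = 59,
                              cfg = forestConfig(n_trees = 5000),
                              positive = "IBC", name = "signature") {
  if (k > nrow(cohort))
    stop("k = ", k, " exceeds the ", nrow(cohort), " genes in the cohort")
  tr <- if (is(design, "MatchedDesign")) design@training_ids
        else design$training_ids
  model <- trainForest(cohort, tr, rownames(cohort), cfg, positive = positive)
  rank <- geneImportance(model)
  top <- rank[seq_len(k), ]
  GeneSignature(top$gene, top$importance, name = name,
                provenance = sprintf(
                  "discovered: %d training samples, %d genes, k=%d, n_trees=%d, seed=%d",
                  length(tr), nrow(cohort), k, cfg@n_trees, cfg@seed))
}

#' Validate a signature by retrained classification
#'
#' Retrains an ensemble restricted to the signature genes on the given
#' training samples, scores every evaluation sample, and reports accuracy
#' over the samples with a known class label. Normal samples count as
#' negatives: the binary model scores them against the positive-class
#' threshold like every other non-positive sample.
#'
#' @param cohort an \linkS4class{ExpressionCohort} used for evaluation.
#' @param sig a \linkS4class{GeneSignature}; all its genes must be
#'   present in the cohort.
#' @param training_ids labeled training sample ids (taken from
#'   \code{training_cohort}).
#' @param cfg a \linkS4class{ForestConfig}.
#' @param training_cohort cohort supplying the training samples; defaults
#'   to \code{cohort} (within-cohort validation). Pass the discovery
#'   cohort here to classify an independent cohort with a model trained
#'   on the discovery samples.
#' @param eval_ids samples to score (default: all cohort samples).
#' @param positive positive class label.
#' @param threshold decision threshold (default 0.5, strict inequality).
#' @return list with \code{model} (\linkS4class{ForestModel}),
#'   \code{result} (\linkS4class{ClassificationResult}) and
#'   \code{accuracy}.
#' @export
validateSignature <- function(cohort, sig, training_ids, cfg = forestConfig(),
                              training_cohort = cohort,
                              eval_ids = colnames(cohort), positive = "IBC",
                              threshold = 0.5) {
  missing_genes <- setdiff(sigGenes(sig), rownames(cohort))
  if (length(missing_genes))
    stop("signature gene(s) missing from validation cohort: ",
         paste(missing_genes, collapse = ", "))
  model <- trainForest(training_cohort, training_ids, sigGenes(sig), cfg,
                       positive = positive)
  result <- predictProba(model, cohort, eval_ids, threshold = threshold)
  labels <- classLabels(cohort)[eval_ids]
  known <- !is.na(labels)
  truth <- ifelse(labels[known] == positive, positive, model@class_order[1])
  acc <- .accuracy(predictedLabels(result)[known], truth)
  list(model = model, result = result, accuracy = acc)
}

#' Random-gene-set null distribution of holdout accuracy
#'
#' Tests signature specificity: per iteration, \code{set_size} genes are
#' sampled uniformly without replacement, an ensemble is trained on the
#' design's training samples with that random set, and its accuracy over
#' the design's holdout samples is recorded — the same samples on which
#' the observed accuracy is computed, so the null and the observation are
#' directly comparable. The empirical p-value uses the add-one formula
#' \eqn{p = (1 + \#\{a \ge observed\}) / (n + 1)}. Iterations draw
#' independent sub-seeds from \code{seed}, so the distribution is
#' reproducible.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param design a \linkS4class{MatchedDesign}.
#' @param set_size genes per random set (default 59).
#' @param n_iterations number of random sets (the reference protocol uses
#'   10000; tests use a few hundred).
#' @param observed_accuracy the signature's accuracy being tested.
#' @param cfg a \linkS4class{ForestConfig}.
#' @param seed integer driving the gene draws and per-iteration training.
#' @param positive positive class label.
#' @return a \linkS4class{NullAccuracyDistribution}.
#' @export
randomSetNull <- function(cohort, design, set_size = 59, n_iterations = 1000,
                          observed_accuracy, cfg = forestConfig(), seed = 1L,
                          positive = "IBC") {
  if (set_size > nrow(cohort))
    stop("set_size = ", set_size, " exceeds the ", nrow(cohort),
         " genes in the cohort")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  genes <- rownames(cohort)
  tr <- design@training_ids
  ho <- design@holdout_ids
  labels <- classLabels(cohort)[ho]
  known <- !is.na(labels)
  neg_lab <- NULL
  acc <- vapply(seq_len(n_iterations), function(i) {
    it_seed <- derive_seed(seed, i)
    gset <- with_seed(it_seed, sample(genes, set_size))
    it_cfg <- forestConfig(n_trees = cfg@n_trees,
                           features_per_split = cfg@features_per_split,
                           min_leaf = cfg@min_leaf, bootstrap = cfg@bootstrap,
                           importance_type = cfg@importance_type,
                           seed = derive_seed(it_seed, 1L))
    model <- trainForest(cohort, tr, gset, it_cfg, positive = positive)
    result <- predictProba(model, cohort, ho)
    truth <- ifelse(labels[known] == positive, positive, model@class_order[1])
    .accuracy(predictedLabels(result)[known], truth)
  }, numeric(1))
  new("NullAccuracyDistribution", accuracies = acc,
      n_iterations = as.integer(n_iterations),
      set_size = as.integer(set_size),
      observed_accuracy = observed_accuracy,
      empirical_p = (1 + sum(acc >= observed_accuracy)) / (n_iterations + 1))
}

setMethod("show", "NullAccuracyDistribution", function(object) {
  cat("NullAccuracyDistribution:", object@n_iterations, "random sets of",
      object@set_size, "genes\n")
  cat(sprintf("  null accuracy mean %.3f (range %.3f-%.3f); observed %.3f; empirical p = %.4g\n",
              mean(object@accuracies), min(object@accuracies),
              max(object@accuracies), object@observed_accuracy,
              object@empirical_p))
})

#' Pairwise overlap of gene signatures
#'
#' Computes pairwise intersection gene lists, counts and Jaccard indices
#' under exact string matching of gene ids, optionally case-folded.
#'
#' @param signatures a named list of \linkS4class{GeneSignature} objects
#'   (at least 2; unnamed entries get their signature name).
#' @param case_fold match gene ids case-insensitively (default FALSE).
#' @return list with \code{counts} and \code{jaccard} matrices and
#'   \code{intersections}, a list of per-pair gene vectors keyed
#'   \code{"A|B"}.
#' @export
compareSignatures <- function(signatures, case_fold = FALSE) {
  if (length(signatures) < 2) stop("need at least 2 signatures")
  nm <- names(signatures)
  if (is.null(nm)) nm <- rep("", length(signatures))
  fallback <- vapply(signatures, function(s) s@name, character(1))
  nm <- ifelse(nzchar(nm), nm, ifelse(nzchar(fallback), fallback,
                                      paste0("sig", seq_along(signatures))))
  sets <- lapply(signatures, function(s) {
    g <- sigGenes(s)
    if (case_fold) toupper(g) else g
  })
  k <- length(sets)
  counts <- matrix(0L, k, k, dimnames = list(nm, nm))
  jac <- matrix(1, k, k, dimnames = list(nm, nm))
  inter <- list()
  for (i in seq_len(k)) {
    counts[i, i] <- length(sets[[i]])
    for (j in seq_len(k)) {
      if (i >= j) next
      common <- intersect(sets[[i]], sets[[j]])
      un <- union(sets[[i]], sets[[j]])
      counts[i, j] <- counts[j, i] <- length(common)
      jac[i, j] <- jac[j, i] <-
        if (length(un)) length(common) / length(un) else 1
      inter[[paste(nm[i], nm[j], sep = "|")]] <- common
    }
  }
  list(counts = counts, jaccard = jac, intersections = inter)
}

#' Benchmark several signatures across cohorts under a uniform protocol
#'
#' For each cohort a single stratified half split is drawn (shared across
#' signatures, so every signature is trained and evaluated on the same
#' samples); each signature is retrained on the training half and scored
#' on the holdout half. Signature genes absent from a cohort are dropped
#' with a warning; a signature that loses more than half of its genes to
#' missingness is flagged non-comparable instead of scored.
#'
#' @param cohorts named list of \linkS4class{ExpressionCohort} objects.
#' @param signatures named list of \linkS4class{GeneSignature} objects.
#' @param cfg a \linkS4class{ForestConfig}; its seed also fixes the
#'   half splits.
#' @param positive positive class label.
#' @return data.frame with columns \code{cohort}, \code{signature},
#'   \code{n_genes_used}, \code{n_genes_missing}, \code{accuracy} (NA
#'   when non-comparable) and \code{comparable}.
#' @export
benchmarkSignatures <- function(cohorts, signatures, cfg = forestConfig(),
                                positive = "IBC") {
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  if (is.null(names(signatures)))
    names(signatures) <- paste0("sig", seq_along(signatures))
  out <- list()
  for (cn in names(cohorts)) {
    cohort <- cohorts[[cn]]
    labels <- classLabels(cohort)
    cls <- setdiff(unique(labels[!is.na(labels)]), "normal")
    split <- splitHalf(cohort, seed = cfg@seed, classes = cls)
    for (sn in names(signatures)) {
      sig <- signatures[[sn]]
      present <- intersect(sigGenes(sig), rownames(cohort))
      n_missing <- length(sigGenes(sig)) - length(present)
      if (n_missing > 0)
        warning(sprintf("%s on %s: %d signature gene(s) absent, dropped",
                        sn, cn, n_missing))
      if (length(present) < length(sigGenes(sig)) / 2 || !length(present)) {
        out[[length(out) + 1]] <- data.frame(
          cohort = cn, signature = sn, n_genes_used = length(present),
          n_genes_missing = n_missing, accuracy = NA_real_,
          comparable = FALSE, stringsAsFactors = FALSE)
        next
      }
      sub <- GeneSignature(present, name = sig@name)
      val <- validateSignature(cohort, sub, split$training_ids, cfg,
                               eval_ids = split$holdout_ids,
                               positive = positive)
      out[[length(out) + 1]] <- data.frame(
        cohort = cn, signature = sn, n_genes_used = length(present),
        n_genes_missing = n_missing, accuracy = val$accuracy,
        comparable = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
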