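#' Configuration of the bagged classification-tree ensemble
#'
#' @param n_trees number of trees (default 500).
#' @param features_per_split candidate features per split: \code{"sqrt"}
#'   (default), \code{"log2"}, \code{"all"} (pure bagging), or an
#'   integer.
#' @param min_leaf minimum terminal-node size (default 1, i.e. trees are
#'   grown to purity).
#' @param bootstrap fit each tree on a bootstrap resample of the training
#'   samples (default TRUE; bootstrap size equals training size).
#' @param importance_type \code{"permutation"} for out-of-bag permutation
#'   importance (mean accuracy decrease; the default) or
#'   \code{"impurity"} for mean Gini decrease.
#' @param seed master seed; one seed drives all per-tree randomness so
#'   training is reproducible.
#' @return a \linkS4class{ForestConfig}.
#' @export
forestConfig <- function(n_trees = 500, features_per_split = "sqrt",
                         min_leaf = 1, bootstrap = TRUE,
                         importance_type = c("permutation", "impurity"),
                         seed = 1L) {
  importance_type <- match.arg(importance_type)
  new("ForestConfig", n_trees = as.integer(n_trees),
      features_per_split = features_per_split,
      min_leaf = as.integer(min_leaf), bootstrap = bootstrap,
      importance_type = importance_type, seed = as.integer(seed))
}

.resolve_mtry <- function(features_per_split, p) {
  m <- if (is.character(features_per_split)) {
    switch(features_per_split,
           sqrt = floor(sqrt(p)), log2 = floor(log2(p)), all = p)
  } else as.integer(features_per_split)
  max(1L, min(as.integer(m), p))
}

#' Train a bagged classification-tree ensemble on a gene set
#'
#' Fits \code{n_trees} classification trees, each on a bootstrap resample
#' of the training samples, restricted to \code{gene_set}. The training
#' labels must be binary over the selected samples; the positive class is
#' listed second in the model's \code{class_order}. Training is a pure
#' function of the data, the config and its seed.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param sample_ids training sample ids (must have non-missing labels).
#' @param gene_set genes to train on (subset of the cohort's genes).
#' @param cfg a \linkS4class{ForestConfig}.
#' @param positive label of the positive class (default \code{"IBC"});
#'   the single remaining observed label is the negative class.
#' @return a \linkS4class{ForestModel}.
#' @export
trainForest <- function(cohort, sample_ids, gene_set, cfg = forestConfig(),
                        positive = "IBC") {
  validObject(cfg)
  missing_genes <- setdiff(gene_set, rownames(cohort))
  if (length(missing_genes))
    stop("gene(s) absent from cohort: ", paste(missing_genes, collapse = ", "))
  labels <- classLabels(cohort)[sample_ids]
  if (any(is.na(labels)))
    stop("unannotated training sample(s): ",
         paste(sample_ids[is.na(labels)], collapse = ", "))
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("training set must contain exactly 2 classes, got: ",
         paste(classes, collapse = ", "))
  if (!positive %in% classes)
    stop("positive class '", positive, "' not present in training labels")
  negative <- setdiff(classes, positive)
  x <- t(exprValues(cohort)[gene_set, sample_ids, drop = FALSE])
  y <- factor(labels, levels = c(negative, positive))
  fit <- with_seed(cfg@seed, randomForest::randomForest(
    x = x, y = y,
    ntree = cfg@n_trees,
    mtry = .resolve_mtry(cfg@features_per_split, length(gene_set)),
    nodesize = cfg@min_leaf,
    replace = cfg@bootstrap,
    importance = TRUE,
    keep.forest = TRUE))
  fit$training_x <- x
  new("ForestModel", config = cfg, gene_set = gene_set, fit = fit,
      class_order = c(negative, positive), training_ids = sample_ids)
}

setMethod("show", "ForestModel", function(object) {
  cat("ForestModel:", object@config@n_trees, "trees over",
      length(object@gene_set), "genes;",
      "classes", paste(object@class_order, collapse = " vs "),
      sprintf("(positive: %s)\n", object@class_order[2]))
  cat("  OOB accuracy:", sprintf("%.3f", oobAccuracy(object)), "\n")
})

#' Gene importance ranking of a fitted ensemble
#'
#' Returns one non-negative score per gene in the model's gene universe,
#' sorted non-increasing. With
#' \code{importance_type = "permutation"} (the default) the score is the
#' out-of-bag permutation importance (mean decrease in accuracy when the
#' gene is permuted in the out-of-bag samples); negative raw values —
#' noise around zero for uninformative genes — are clamped to 0, which
#' leaves the ranking of informative genes unchanged. With
#' \code{"impurity"} it is the mean decrease in Gini impurity. The
#' ranking is deterministic for a fixed training seed; ties are broken by
#' gene id.
#'
#' @param model a fitted \linkS4class{ForestModel}.
#' @return data.frame with columns \code{gene} and \code{importance},
#'   one row per gene of the model's universe, sorted by non-increasing
#'   importance.
#' @export
geneImportance <- function(model) {
  if (!is(model@fit, "randomForest")) stop("model is not fitted")
  type <- if (model@config@importance_type == "permutation") 1 else 2
  imp <- randomForest::importance(model@fit, type = type, scale = FALSE)[, 1]
  imp <- pmax(imp, 0)
  ord <- order(-imp, names(imp))
  data.frame(gene = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Out-of-bag accuracy of a fitted ensemble
#'
#' Accuracy of the out-of-bag class votes on the training samples — an
#' unbiased internal error estimate under bagging.
#'
#' @param model a fitted \linkS4class{ForestModel}.
#' @return a number in [0, 1].
#' @export
oobAccuracy <- function(model) {
  if (!is(model@fit, "randomForest")) stop("model is not fitted")
  pred <- model@fit$predicted
  mean(as.character(pred) == as.character(model@fit$y), na.rm = TRUE)
}

#' Ensemble probability scores for cohort samples
#'
#' The probability score of a sample is the fraction of trees voting the
#' positive class; the sample is called positive iff its score is
#' strictly greater than \code{threshold}, so a score of exactly 0.5 at
#' the default threshold is labeled negative. Scores lie on the grid
#' \code{k / n_trees}.
#'
#' @param model a fitted \linkS4class{ForestModel}.
#' @param cohort an \linkS4class{ExpressionCohort} containing every model
#'   gene.
#' @param sample_ids samples to score (default: all cohort samples).
#' @param threshold decision threshold (default 0.5).
#' @return a \linkS4class{ClassificationResult}.
#' @export
predictProba <- function(model, cohort, sample_ids = colnames(cohort),
                         threshold = 0.5) {
  if (!is(model@fit, "randomForest")) stop("model is not fitted")
  missing_genes <- setdiff(model@gene_set, rownames(cohort))
  if (length(missing_genes))
    stop("model gene(s) missing from cohort: ",
         paste(missing_genes, collapse = ", "))
  x <- t(exprValues(cohort)[model@gene_set, sample_ids, drop = FALSE])
  votes <- stats::predict(model@fit, newdata = x, type = "vote",
                          norm.votes = TRUE)
  score <- votes[, model@class_order[2]]
  lab <- ifelse(score > threshold, model@class_order[2], model@class_order[1])
  new("ClassificationResult", sample_ids = sample_ids,
      prob_score = unname(score), predicted_label = unname(lab),
      threshold = threshold, class_order = model@class_order)
}

#' Serialize / restore a forest model as human-readable text
#'
#' The model file records the config (including the seed), the class
#' order, the gene set, and the training labels and expression submatrix.
#' Because training is a pure function of (data, config, seed),
#' [readForestModel()] re-instantiates the exact classification behavior
#' by deterministic retraining on load (given the same library
#' versions).
#'
#' @param model a fitted \linkS4class{ForestModel}.
#' @param path output file path.
#' @return \code{writeForestModel} invisibly returns \code{path};
#'   \code{readForestModel} returns a fitted \linkS4class{ForestModel}.
#' @export
writeForestModel <- function(model, path) {
  cfg <- model@config
  x <- exprValues_of_fit(model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# ibcsig forest model v1",
    paste0("n_trees: ", cfg@n_trees),
    paste0("features_per_split: ", cfg@features_per_split),
    paste0("min_leaf: ", cfg@min_leaf),
    paste0("bootstrap: ", cfg@bootstrap),
    paste0("importance_type: ", cfg@importance_type),
    paste0("seed: ", cfg@seed),
    paste0("class_order: ", paste(model@class_order, collapse = "\t")),
    paste0("genes: ", paste(model@gene_set, collapse = "\t")),
    paste0("training_ids: ", paste(model@training_ids, collapse = "\t")),
    paste0("training_labels: ",
           paste(as.character(model@fit$y), collapse = "\t")),
    "training_matrix:"), con)
  for (i in seq_len(nrow(x)))
    writeLines(paste(format(x[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = "\t"), con)
  invisible(path)
}

# training matrix (samples x genes) as used at fit time
exprValues_of_fit <- function(model) {
  x <- model@fit$training_x
  if (is.null(x)) stop("model carries no training matrix")
  x
}

#' @rdname writeForestModel
#' @export
readForestModel <- function(path) {
  lines <- readLines(path)
  get1 <- function(key) {
    ln <- grep(paste0("^", key, ": "), lines, value = TRUE)
    if (!length(ln)) stop("malformed model file: missing '", key, "'")
    sub(paste0("^", key, ": "), "", ln[1])
  }
  fps <- get1("features_per_split")
  if (!fps %in% c("sqrt", "log2", "all")) fps <- as.integer(fps)
  cfg <- forestConfig(n_trees = as.integer(get1("n_trees")),
                      features_per_split = fps,
                      min_leaf = as.integer(get1("min_leaf")),
                      bootstrap = as.logical(get1("bootstrap")),
                      importance_type = get1("importance_type"),
                      seed = as.integer(get1("seed")))
  class_order <- strsplit(get1("class_order"), "\t", fixed = TRUE)[[1]]
  genes <- strsplit(get1("genes"), "\t", fixed = TRUE)[[1]]
  ids <- strsplit(get1("training_ids"), "\t", fixed = TRUE)[[1]]
  labels <- strsplit(get1("training_labels"), "\t", fixed = TRUE)[[1]]
  start <- which(lines == "training_matrix:")
  if (!length(start)) stop("malformed model file: missing training_matrix")
  rows <- lines[(start + 1):(start + length(ids))]
  x <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE), as.numeric))
  dimnames(x) <- list(ids, genes)
  m <- matrix(t(x), ncol = length(ids),
              dimnames = list(genes, ids))
  ann <- data.frame(sample_id = ids, class_label = labels,
                    stringsAsFactors = FALSE)
  cohort <- ExpressionCohort(m, ann)
  trainForest(cohort, ids, genes, cfg, positive = class_order[2])
}
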