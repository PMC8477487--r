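#' @import methods
#' @importFrom stats cor dist hclust cutree prcomp rnorm runif rexp rbinom
#'   quantile sd var pchisq setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' ExpressionCohort: a labeled log2 expression cohort
#'
#' An \code{ExpressionCohort} holds a genes-by-samples matrix of
#' log2-scale expression values together with aligned per-sample
#' annotations, stored as a \linkS4class{SummarizedExperiment} with a
#' single assay named \code{"exprs"}. Annotation columns are
#' \code{class_label} (\code{"IBC"}, \code{"nonIBC"}, \code{"normal"} or
#' \code{NA}), \code{er_score} and \code{her2_score} (ordinal
#' immunohistochemistry scores or \code{NA}), \code{treatment}
#' (\code{"pre"}, \code{"post"} or \code{NA}), and \code{surv_time} /
#' \code{surv_event} for survival follow-up.
#'
#' Values are required to be finite: the tree ensembles used downstream
#' are defined on complete matrices, so missing expression is rejected at
#' construction. Values are assumed already log2-transformed and
#' normalized; the package performs no normalization.
#'
#' @slot (inherited) see \linkS4class{SummarizedExperiment}.
#' @seealso [ExpressionCohort()], [readCohort()]
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

.cohort_annotation_cols <- c("class_label", "er_score", "her2_score",
                             "treatment", "surv_time", "surv_event")
.class_levels <- c("IBC", "nonIBC", "normal")

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  m <- SummarizedExperiment::assay(object, "exprs")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "expression matrix must have gene rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, paste0("duplicate gene ids: ",
                           paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, paste0("duplicate sample ids: ",
                           paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must all be finite (no NA/NaN/Inf)")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.cohort_annotation_cols, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing annotation columns: ", paste(miss, collapse = ", ")))
  if ("class_label" %in% colnames(cd)) {
    bad <- setdiff(unique(cd$class_label[!is.na(cd$class_label)]), .class_levels)
    if (length(bad))
      msg <- c(msg, paste0("unknown class_label values: ", paste(bad, collapse = ", ")))
  }
  if ("surv_event" %in% colnames(cd)) {
    ev <- cd$surv_event
    if (!all(is.na(ev) | ev %in% c(0, 1)))
      msg <- c(msg, "surv_event must be 0, 1 or NA")
  }
  if (length(msg)) msg else TRUE
})

#' GeneSignature: an ordered gene list with importance scores
#'
#' Genes are ordered by non-increasing importance (when importance is
#' present). Duplicate gene ids are rejected.
#'
#' @slot genes character vector of unique gene identifiers, in rank order.
#' @slot importance numeric vector aligned to \code{genes} (non-negative,
#'   non-increasing) or length zero when scores are unavailable.
#' @slot name free-text signature name.
#' @slot provenance free-text provenance (cohort, parameters).
#' @seealso [readSignature()], [writeSignature()], [discoverSignature()]
#' @export
setClass("GeneSignature",
         representation(genes = "character", importance = "numeric",
                        name = "character", provenance = "character"),
         prototype(genes = character(), importance = numeric(),
                   name = "", provenance = ""))

setValidity("GeneSignature", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes))
    msg <- c(msg, paste0("duplicate genes in signature: ",
                         paste(unique(object@genes[duplicated(object@genes)]), collapse = ", ")))
  if (length(object@importance)) {
    if (length(object@importance) != length(object@genes))
      msg <- c(msg, "importance must align 1:1 with genes")
    else {
      if (any(object@importance < 0))
        msg <- c(msg, "importance scores must be non-negative")
      if (is.unsorted(-object@importance))
        msg <- c(msg, "importance scores must be sorted non-increasing")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ClassificationResult: per-sample ensemble probability scores
#'
#' The probability score is the fraction of ensemble trees voting the
#' positive class; a sample is called positive iff its score is strictly
#' greater than the threshold (default 0.5), so a score of exactly 0.5 is
#' labeled negative.
#'
#' @slot sample_ids character sample identifiers.
#' @slot prob_score numeric in [0, 1], aligned to \code{sample_ids}.
#' @slot predicted_label character, positive/negative class labels.
#' @slot threshold numeric scalar decision threshold.
#' @slot class_order character of length 2: (negative, positive).
#' @export
setClass("ClassificationResult",
         representation(sample_ids = "character", prob_score = "numeric",
                        predicted_label = "character", threshold = "numeric",
                        class_order = "character"))

setValidity("ClassificationResult", function(object) {
  msg <- character()
  n <- length(object@sample_ids)
  if (length(object@prob_score) != n || length(object@predicted_label) != n)
    msg <- c(msg, "sample_ids, prob_score, predicted_label must align")
  if (any(object@prob_score < 0 | object@prob_score > 1))
    msg <- c(msg, "prob_score must lie in [0, 1]")
  if (length(object@class_order) != 2)
    msg <- c(msg, "class_order must name (negative, positive)")
  else {
    want <- ifelse(object@prob_score > object@threshold,
                   object@class_order[2], object@class_order[1])
    if (!identical(unname(want), unname(object@predicted_label)))
      msg <- c(msg, "predicted_label must equal positive iff prob_score > threshold")
  }
  if (length(msg)) msg else TRUE
})

#' ForestConfig: hyperparameters of the bagged-tree ensemble
#'
#' @slot n_trees number of trees (default 500).
#' @slot features_per_split \code{"sqrt"}, \code{"log2"}, \code{"all"} or
#'   a positive integer: candidate features per split.
#' @slot min_leaf minimum terminal-node size (default 1).
#' @slot bootstrap draw bootstrap resamples (default TRUE).
#' @slot importance_type \code{"permutation"} (out-of-bag mean accuracy
#'   decrease, the default) or \code{"impurity"}.
#' @slot seed integer master seed; training is a pure function of
#'   (data, config, seed).
#' @seealso [forestConfig()]
#' @export
setClass("ForestConfig",
         representation(n_trees = "integer", features_per_split = "ANY",
                        min_leaf = "integer", bootstrap = "logical",
                        importance_type = "character", seed = "integer"))

setValidity("ForestConfig", function(object) {
  msg <- character()
  if (object@n_trees < 1L) msg <- c(msg, "n_trees must be >= 1")
  if (object@min_leaf < 1L) msg <- c(msg, "min_leaf must be >= 1")
  f <- object@features_per_split
  ok <- (is.character(f) && length(f) == 1 && f %in% c("sqrt", "log2", "all")) ||
    (is.numeric(f) && length(f) == 1 && f >= 1)
  if (!ok) msg <- c(msg, "features_per_split must be 'sqrt', 'log2', 'all' or a positive integer")
  if (!object@importance_type %in% c("permutation", "impurity"))
    msg <- c(msg, "importance_type must be 'permutation' or 'impurity'")
  if (length(msg)) msg else TRUE
})

#' ForestModel: a fitted bagged classification-tree ensemble
#'
#' Wraps a fitted ensemble restricted to a fixed gene set; prediction
#' requires exactly those genes. \code{class_order} is
#' (negative, positive).
#'
#' @slot config a \linkS4class{ForestConfig}.
#' @slot gene_set ordered genes the model consumes.
#' @slot fit fitted \code{randomForest} state (opaque).
#' @slot class_order character of length 2: (negative, positive).
#' @slot training_ids sample ids the model was fitted on.
#' @export
setClass("ForestModel",
         representation(config = "ForestConfig", gene_set = "character",
                        fit = "ANY", class_order = "character",
                        training_ids = "character"))

#' MatchedDesign: receptor-matched training design
#'
#' Pairs positive and negative samples with identical (ER, HER2) scores;
#' training ids are the flattened pairs plus any unmatched fill-ins, and
#' holdout ids are every remaining cohort sample (including normals).
#'
#' @slot pairs data.frame with columns \code{positive}, \code{negative},
#'   \code{er_score}, \code{her2_score} (matched pairs only).
#' @slot training_ids character, unique training sample ids.
#' @slot holdout_ids character, all remaining cohort samples.
#' @slot unmatched_ids character, training samples appended without an
#'   exact-score partner.
#' @seealso [matchTrainingSet()]
#' @export
setClass("MatchedDesign",
         representation(pairs = "data.frame", training_ids = "character",
                        holdout_ids = "character", unmatched_ids = "character"))

setValidity("MatchedDesign", function(object) {
  msg <- character()
  ids <- c(object@pairs$positive, object@pairs$negative, object@unmatched_ids)
  if (anyDuplicated(ids))
    msg <- c(msg, "a sample may appear in at most one pair")
  if (!setequal(ids, object@training_ids))
    msg <- c(msg, "training_ids must be the flattened pairs plus unmatched fill-ins")
  if (length(intersect(object@training_ids, object@holdout_ids)))
    msg <- c(msg, "training and holdout ids must be disjoint")
  if (length(msg)) msg else TRUE
})

#' NullAccuracyDistribution: random-gene-set null of holdout accuracy
#'
#' Accuracies of ensembles trained on uniformly random size-matched gene
#' sets, with the add-one empirical p-value
#' \eqn{p = (1 + \#\{a \ge observed\}) / (n + 1)}.
#'
#' @slot accuracies numeric in [0, 1], one per iteration.
#' @slot n_iterations integer.
#' @slot set_size integer, genes per random set.
#' @slot observed_accuracy numeric, the signature's accuracy being tested.
#' @slot empirical_p numeric in (0, 1].
#' @seealso [randomSetNull()]
#' @export
setClass("NullAccuracyDistribution",
         representation(accuracies = "numeric", n_iterations = "integer",
                        set_size = "integer", observed_accuracy = "numeric",
                        empirical_p = "numeric"))

setValidity("NullAccuracyDistribution", function(object) {
  msg <- character()
  if (length(object@accuracies) != object@n_iterations)
    msg <- c(msg, "accuracies must have one entry per iteration")
  if (any(object@accuracies < 0 | object@accuracies > 1))
    msg <- c(msg, "accuracies must lie in [0, 1]")
  p_expect <- (1 + sum(object@accuracies >= object@observed_accuracy)) /
    (object@n_iterations + 1)
  if (abs(object@empirical_p - p_expect) > 1e-12)
    msg <- c(msg, "empirical_p must follow the add-one formula")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of the synthetic-cohort simulator
#'
#' Defaults emulate the discovery cohort structure the analysis assumes:
#' 2000 genes, 20 IBC / 20 nonIBC / 5 normal samples, 59 planted
#' signature genes with a bidirectional 1.5-SD log2 shift in the IBC
#' class, unit Gaussian noise, a batch-shifted validation cohort
#' (global offset 0.5, per-gene jitter SD 0.3), post-treatment
#' attenuation 0.2, and exponential survival with hazard ratio 3.15 for
#' the positive class.
#'
#' @slot n_genes total genes.
#' @slot n_per_class named integer vector of per-class sample counts.
#' @slot n_signal number of planted signature genes.
#' @slot effect_size mean log2 shift of planted genes in the positive
#'   class, in units of \code{noise_sd}.
#' @slot noise_sd per-gene Gaussian noise SD on the log2 scale.
#' @slot batch_shift numeric of length 2: global additive offset and
#'   per-gene jitter SD applied to validation cohorts.
#' @slot attenuation multiplier in [0, 1] applied to the planted effect
#'   in post-treatment samples.
#' @slot receptor_config list: \code{pairs} (two-column matrix of
#'   (ER, HER2) grid points), \code{probs} (sampling probabilities) and
#'   \code{match_fraction} (fraction of negatives whose scores copy a
#'   positive's, guaranteeing an exact-matchable subset).
#' @slot survival_config list: \code{baseline_hazard}, \code{hazard_ratio}
#'   for the positive class, \code{censor_rate}.
#' @slot noise_family \code{"gaussian"} (default) or \code{"laplace"}.
#' @slot seed integer.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
         representation(n_genes = "integer", n_per_class = "integer",
                        n_signal = "integer", effect_size = "numeric",
                        noise_sd = "numeric", batch_shift = "numeric",
                        attenuation = "numeric", receptor_config = "list",
                        survival_config = "list", noise_family = "character",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_signal > object@n_genes)
    msg <- c(msg, "n_signal must not exceed n_genes")
  if (object@attenuation < 0 || object@attenuation > 1)
    msg <- c(msg, "attenuation must lie in [0, 1]")
  if (any(object@n_per_class < 1L))
    msg <- c(msg, "all class counts must be positive")
  if (is.null(names(object@n_per_class)))
    msg <- c(msg, "n_per_class must be named by class")
  if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be positive")
  if (length(object@batch_shift) != 2)
    msg <- c(msg, "batch_shift must be (offset, jitter sd)")
  sc <- object@survival_config
  if (!is.null(sc$hazard_ratio) && sc$hazard_ratio <= 0)
    msg <- c(msg, "hazard_ratio must be positive")
  if (!object@noise_family %in% c("gaussian", "laplace"))
    msg <- c(msg, "noise_family must be 'gaussian' or 'laplace'")
  if (length(msg)) msg else TRUE
})

#' SimulationTruth: ground truth of a simulated cohort
#'
#' @slot planted_genes ids of the genes carrying the class effect.
#' @slot planted_sign named numeric (+1/-1) effect direction per planted
#'   gene.
#' @slot baseline named numeric per-gene baseline means.
#' @slot true_class named character per-sample true class.
#' @slot true_hazard_ratio numeric.
#' @export
setClass("SimulationTruth",
         representation(planted_genes = "character", planted_sign = "numeric",
                        baseline = "numeric", true_class = "character",
                        true_hazard_ratio = "numeric"))

#' CentroidPanel: nearest-centroid subtype panel with ROR coefficients
#'
#' Five intrinsic-subtype centroids over a panel gene list, plus the
#' risk-of-recurrence (ROR) linear coefficients and affine scaling
#' constants. The panel is pluggable: any centroid/coefficient set in the
#' panel file format can be supplied.
#'
#' @slot genes panel gene ids.
#' @slot centroids genes-by-subtype numeric matrix.
#' @slot ror_coefficients named numeric, one coefficient per subtype.
#' @slot ror_intercept,ror_scale affine constants:
#'   ROR = intercept + scale * sum(coef * correlation).
#' @seealso [readCentroidPanel()], [pam50Call()]
#' @export
setClass("CentroidPanel",
         representation(genes = "character", centroids = "matrix",
                        ror_coefficients = "numeric", ror_intercept = "numeric",
                        ror_scale = "numeric"))

setValidity("CentroidPanel", function(object) {
  msg <- character()
  if (ncol(object@centroids) != 5L)
    msg <- c(msg, "panel must have exactly 5 subtype centroids")
  if (nrow(object@centroids) != length(object@genes))
    msg <- c(msg, "centroid vectors must align to the panel gene list")
  if (!identical(sort(names(object@ror_coefficients)),
                 sort(colnames(object@centroids))))
    msg <- c(msg, "ROR coefficients must be named by subtype")
  if (!all(is.finite(object@centroids)) ||
      !all(is.finite(object@ror_coefficients)) ||
      !is.finite(object@ror_intercept) || !is.finite(object@ror_scale))
    msg <- c(msg, "panel values and coefficients must be finite")
  if (length(msg)) msg else TRUE
})

#' SubtypeCall: per-sample nearest-centroid subtype assignments
#'
#' @slot sample_ids character.
#' @slot subtype per-sample subtype label (argmax correlation,
#'   deterministic tie-break by panel subtype order).
#' @slot correlations samples-by-subtype matrix of rank correlations in
#'   [-1, 1].
#' @slot ror_score per-sample risk-of-recurrence score.
#' @export
setClass("SubtypeCall",
         representation(sample_ids = "character", subtype = "character",
                        correlations = "matrix", ror_score = "numeric"))

setValidity("SubtypeCall", function(object) {
  msg <- character()
  if (any(object@correlations < -1 - 1e-9 | object@correlations > 1 + 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  lab <- colnames(object@correlations)[max.col(object@correlations,
                                               ties.method = "first")]
  if (!identical(unname(lab), unname(object@subtype)))
    msg <- c(msg, "subtype must be the argmax-correlation label")
  if (length(msg)) msg else TRUE
})

#' SurvivalTable: per-sample survival follow-up with group labels
#'
#' @slot sample_ids character.
#' @slot time non-negative follow-up times.
#' @slot event 0/1 event indicators (1 = event observed).
#' @slot group per-sample group label.
#' @seealso [survivalTable()], [kmCurve()], [logrankHr()]
#' @export
setClass("SurvivalTable",
         representation(sample_ids = "character", time = "numeric",
                        event = "numeric", group = "character"))

setValidity("SurvivalTable", function(object) {
  msg <- character()
  n <- length(object@sample_ids)
  if (length(object@time) != n || length(object@event) != n ||
      length(object@group) != n)
    msg <- c(msg, "time, event and group must align with sample_ids")
  if (any(object@time < 0)) msg <- c(msg, "times must be non-negative")
  if (!all(object@event %in% c(0, 1)))
    msg <- c(msg, "event must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' ClusteringResult: hierarchical clustering with CH model selection
#'
#' @slot hclust the agglomerative tree (merge order + heights).
#' @slot labels samples-by-k matrix of flat cluster labels for
#'   k = 2..k_max.
#' @slot ch_scores named numeric, Calinski-Harabasz index per k (NA when
#'   degenerate).
#' @slot optimal_k the argmax of \code{ch_scores}.
#' @seealso [hierCluster()], [chIndex()]
#' @export
setClass("ClusteringResult",
         representation(hclust = "ANY", labels = "matrix",
                        ch_scores = "numeric", optimal_k = "integer"))

#' PcaProjection: principal-component projection of samples
#'
#' @slot coordinates samples-by-component score matrix.
#' @slot explained_variance fraction of variance per component
#'   (non-increasing, sums to at most 1).
#' @seealso [pcaProject()]
#' @export
setClass("PcaProjection",
         representation(coordinates = "matrix", explained_variance = "numeric"))

setValidity("PcaProjection", function(object) {
  msg <- character()
  ev <- object@explained_variance
  if (length(ev) && (is.unsorted(-(ev + 1e-12)) || sum(ev) > 1 + 1e-8))
    msg <- c(msg, "explained-variance fractions must be non-increasing and sum to <= 1")
  if (length(msg)) msg else TRUE
})
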