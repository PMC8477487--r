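#' Construct a receptor-matched training design
#'
#' Pairs positive and negative samples with identical (ER, HER2) score
#' pairs to control molecular-subtype confounding in signature discovery.
#' Within each score stratum the matching is maximum-cardinality (any
#' positive can pair with any negative of the same stratum, so the
#' maximum is \code{min(n_pos, n_neg)} per stratum); candidates are taken
#' in lexicographic sample-id order, making the design deterministic and
#' invariant to input sample order. Up to \code{allow_unmatched} extra
#' samples per class are then appended unmatched, chosen as the remaining
#' (positive, negative) pairs whose (ER, HER2) scores are nearest in L1
#' distance on the score grid (ties broken lexicographically by id).
#' Holdout ids are every other cohort sample, including normals.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param allow_unmatched maximum unmatched samples appended per class
#'   (default 0).
#' @param positive,negative class labels defining the two arms.
#' @return a \linkS4class{MatchedDesign}.
#' @examples
#' sim <- simulateCohort(simulationConfig(n_genes = 100, seed = 3))
#' design <- matchTrainingSet(sim$cohort, allow_unmatched = 1)
#' length(trainingIds(design))
#' @export
matchTrainingSet <- function(cohort, allow_unmatched = 0,
                             positive = "IBC", negative = "nonIBC") {
  labels <- classLabels(cohort)
  rec <- receptorScores(cohort)
  pos_ids <- sort(names(labels)[!is.na(labels) & labels == positive])
  neg_ids <- sort(names(labels)[!is.na(labels) & labels == negative])
  if (!length(pos_ids) || !length(neg_ids))
    stop("cohort must contain annotated '", positive, "' and '", negative,
         "' samples")
  cand <- c(pos_ids, neg_ids)
  no_score <- cand[is.na(rec[cand, "er_score"]) | is.na(rec[cand, "her2_score"])]
  if (length(no_score))
    stop("missing receptor score for candidate sample(s): ",
         paste(no_score, collapse = ", "))
  stratum <- paste(rec[cand, "er_score"], rec[cand, "her2_score"], sep = "/")
  names(stratum) <- cand
  pairs <- data.frame(positive = character(), negative = character(),
                      er_score = numeric(), her2_score = numeric(),
                      stringsAsFactors = FALSE)
  for (s in sort(unique(stratum))) {
    p <- pos_ids[stratum[pos_ids] == s]
    n <- neg_ids[stratum[neg_ids] == s]
    k <- min(length(p), length(n))
    if (k > 0) {
      sc <- rec[p[1], ]
      pairs <- rbind(pairs, data.frame(
        positive = p[seq_len(k)], negative = n[seq_len(k)],
        er_score = sc$er_score, her2_score = sc$her2_score,
        stringsAsFactors = FALSE))
    }
  }
  unmatched <- character(0)
  if (allow_unmatched > 0) {
    rem_p <- setdiff(pos_ids, pairs$positive)
    rem_n <- setdiff(neg_ids, pairs$negative)
    n_fill <- min(allow_unmatched, length(rem_p), length(rem_n))
    for (i in seq_len(n_fill)) {
      d <- outer(seq_along(rem_p), seq_along(rem_n), function(ip, jn) {
        abs(rec[rem_p[ip], "er_score"] - rec[rem_n[jn], "er_score"]) +
          abs(rec[rem_p[ip], "her2_score"] - rec[rem_n[jn], "her2_score"])
      })
      best <- which(d == min(d), arr.ind = TRUE)
      best <- best[order(rem_p[best[, 1]], rem_n[best[, 2]]), , drop = FALSE]
      unmatched <- c(unmatched, rem_p[best[1, 1]], rem_n[best[1, 2]])
      rem_p <- rem_p[-best[1, 1]]
      rem_n <- rem_n[-best[1, 2]]
    }
  }
  training <- c(pairs$positive, pairs$negative, unmatched)
  if (!length(training))
    stop("no exactly matchable (ER, HER2) pairs and allow_unmatched = 0: ",
         "empty design")
  new("MatchedDesign", pairs = pairs, training_ids = training,
      holdout_ids = setdiff(colnames(cohort), training),
      unmatched_ids = unmatched)
}

#' @describeIn matchTrainingSet training sample ids of a design.
#' @param design a \linkS4class{MatchedDesign}.
#' @export
trainingIds <- function(design) design@training_ids

#' @describeIn matchTrainingSet holdout sample ids of a design.
#' @export
holdoutIds <- function(design) design@holdout_ids

#' @describeIn matchTrainingSet the matched pairs as a data.frame.
#' @export
matchedPairs <- function(design) design@pairs

setMethod("show", "MatchedDesign", function(object) {
  cat("MatchedDesign:", nrow(object@pairs), "matched pairs,",
      length(object@unmatched_ids), "unmatched fill-ins;",
      length(object@training_ids), "training /",
      length(object@holdout_ids), "holdout samples\n")
})

#' Stratified half split of a labeled cohort
#'
#' Splits the samples of each class in half at random, assigning the
#' extra sample of an odd-sized class to training (ceiling to training,
#' floor to holdout). Only samples with a non-missing class label among
#' \code{classes} are split; a pure function of \code{seed}.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param seed integer.
#' @param classes class labels to split (default: all observed labels).
#' @return list with \code{training_ids} and \code{holdout_ids}.
#' @export
splitHalf <- function(cohort, seed, classes = NULL) {
  labels <- classLabels(cohort)
  labels <- labels[!is.na(labels)]
  if (is.null(classes)) classes <- sort(unique(labels))
  training <- character(0); holdout <- character(0)
  for (cl in classes) {
    ids <- sort(names(labels)[labels == cl])
    if (length(ids) < 2)
      stop("class '", cl, "' has fewer than 2 samples; cannot half-split")
    n_tr <- ceiling(length(ids) / 2)
    tr <- with_seed(derive_seed(seed, match(cl, classes)),
                    sample(ids, n_tr))
    training <- c(training, sort(tr))
    holdout <- c(holdout, setdiff(ids, tr))
  }
  list(training_ids = training, holdout_ids = holdout)
}
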