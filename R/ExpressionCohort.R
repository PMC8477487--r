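#' Construct an ExpressionCohort
#'
#' @param values genes-by-samples numeric matrix of log2 expression with
#'   gene rownames and sample colnames. All values must be finite.
#' @param annotations data.frame of per-sample annotations with a
#'   \code{sample_id} column (or sample-id rownames). Recognised columns:
#'   \code{class_label}, \code{er_score}, \code{her2_score},
#'   \code{treatment}, \code{surv_time}, \code{surv_event}. Samples in
#'   the matrix but absent from \code{annotations} get all-missing
#'   fields. \code{NULL} leaves every sample unannotated.
#'
#' @return An \linkS4class{ExpressionCohort}. Matrix column order defines
#'   sample order.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(paste0("G", 1:3), c("s1", "s2")))
#' ann <- data.frame(sample_id = c("s1", "s2"),
#'                   class_label = c("IBC", "nonIBC"))
#' ExpressionCohort(m, ann)
#' @export
ExpressionCohort <- function(values, annotations = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values))
    stop("expression values must be numeric")
  sample_ids <- colnames(values)
  cd <- data.frame(row.names = sample_ids,
                   class_label = rep(NA_character_, length(sample_ids)),
                   er_score = NA_real_, her2_score = NA_real_,
                   treatment = NA_character_, surv_time = NA_real_,
                   surv_event = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if ("sample_id" %in% colnames(annotations)) {
      ids <- as.character(annotations$sample_id)
    } else {
      ids <- rownames(annotations)
    }
    if (anyDuplicated(ids))
      stop("duplicate sample ids in annotations: ",
           paste(.dup_names(ids), collapse = ", "))
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown))
      stop("annotated sample ids absent from the expression matrix: ",
           paste(unknown, collapse = ", "))
    for (col in intersect(.cohort_annotation_cols, colnames(annotations))) {
      v <- annotations[[col]]
      if (col %in% c("class_label", "treatment")) {
        v <- as.character(v)
        v[!is.na(v) & v == ""] <- NA_character_
      } else v <- as.numeric(v)
      cd[ids, col] <- v
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(cd))
  new("ExpressionCohort", se)
}

#' @describeIn ExpressionCohort the genes-by-samples log2 expression matrix.
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @export
exprValues <- function(cohort) SummarizedExperiment::assay(cohort, "exprs")

#' @describeIn ExpressionCohort per-sample class labels (named character).
#' @export
classLabels <- function(cohort) {
  setNames(SummarizedExperiment::colData(cohort)$class_label, colnames(cohort))
}

#' @describeIn ExpressionCohort per-sample (ER, HER2) receptor scores as a
#'   two-column data.frame.
#' @export
receptorScores <- function(cohort) {
  cd <- SummarizedExperiment::colData(cohort)
  data.frame(row.names = colnames(cohort),
             er_score = cd$er_score, her2_score = cd$her2_score)
}

#' @describeIn ExpressionCohort full annotation table as a data.frame.
#' @export
sampleAnnotations <- function(cohort) {
  as.data.frame(SummarizedExperiment::colData(cohort))[, .cohort_annotation_cols]
}

setMethod("show", "ExpressionCohort", function(object) {
  tab <- table(classLabels(object), useNA = "no")
  cat("ExpressionCohort:", nrow(object), "genes x", ncol(object), "samples\n")
  if (length(tab))
    cat("  classes:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  n_na <- sum(is.na(classLabels(object)))
  if (n_na) cat("  unannotated samples:", n_na, "\n")
})
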