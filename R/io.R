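#' Read an expression cohort from delimited text
#'
#' The matrix file is genes-in-rows / samples-in-columns with the gene id
#' in the first column and a header row of sample ids — the de-facto GEO
#' series-matrix-like layout after metadata stripping. The annotation
#' file has one row per sample with named columns; \code{class_label} is
#' required there, the remaining columns
#' (\code{er_score}, \code{her2_score}, \code{treatment},
#' \code{surv_time}, \code{surv_event}) are optional. The delimiter is
#' auto-detected from the extension (\code{.csv} = comma, otherwise
#' tab); ids are case-sensitive.
#'
#' @param matrix_path path to the expression matrix file.
#' @param annotation_path optional path to the sample annotation file; it
#'   must contain a \code{sample_id} column.
#' @return a validated \linkS4class{ExpressionCohort}; samples present in
#'   the matrix but absent from the annotations get all-missing fields,
#'   and the matrix column order defines sample order.
#' @export
readCohort <- function(matrix_path, annotation_path = NULL) {
  sep <- .delim_for(matrix_path)
  raw <- read.delim(matrix_path, sep = sep, header = TRUE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression matrix needs a gene-id column and >= 1 sample")
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", matrix_path, ": ",
         paste(.dup_names(gene_ids), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in ", matrix_path, ": ",
         paste(.dup_names(sample_ids), collapse = ", "))
  m <- matrix(NA_real_, nrow(raw), length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- sort(unique(c(which(is.na(v)), which(raw[[j + 1]] %in% c("NA", "")))))
    if (length(bad))
      stop("non-numeric or missing expression value at gene '",
           gene_ids[bad[1]], "' (row ", bad[1], "), sample '",
           sample_ids[j], "' (column ", j + 1, ") in ", matrix_path)
    m[, j] <- v
  }
  ann <- NULL
  if (!is.null(annotation_path)) {
    ann <- read.delim(annotation_path, sep = .delim_for(annotation_path),
                      header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(ann))
      stop("annotation file must have a 'sample_id' column")
  }
  ExpressionCohort(m, ann)
}

#' Write an expression cohort to delimited text
#'
#' Inverse of [readCohort()]: writes the matrix (gene ids in the first
#' column) and, optionally, the annotation table.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param matrix_path output path for the matrix.
#' @param annotation_path optional output path for annotations.
#' @return invisibly, \code{matrix_path}.
#' @export
writeCohort <- function(cohort, matrix_path, annotation_path = NULL) {
  m <- exprValues(cohort)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, matrix_path, sep = .delim_for(matrix_path),
              quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- data.frame(sample_id = colnames(cohort),
                      sampleAnnotations(cohort), check.names = FALSE)
    write.table(ann, annotation_path, sep = .delim_for(annotation_path),
                quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Construct a GeneSignature
#'
#' @param genes character vector of unique gene ids, ordered by rank.
#' @param importance optional aligned non-negative scores, non-increasing.
#' @param name,provenance free text.
#' @return a \linkS4class{GeneSignature}.
#' @export
GeneSignature <- function(genes, importance = numeric(), name = "",
                          provenance = "") {
  new("GeneSignature", genes = as.character(genes),
      importance = as.numeric(importance), name = name,
      provenance = provenance)
}

#' @describeIn GeneSignature the ordered gene ids.
#' @param sig a \linkS4class{GeneSignature}.
#' @export
sigGenes <- function(sig) sig@genes

#' @describeIn GeneSignature the aligned importance scores (length zero
#'   when absent).
#' @export
sigImportance <- function(sig) setNames(sig@importance, sig@genes[seq_along(sig@importance)])

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature", if (nzchar(object@name)) sQuote(object@name) else "",
      "with", length(object@genes), "genes\n")
  if (length(object@genes))
    cat("  top genes:", paste(head(object@genes, 5), collapse = ", "),
        if (length(object@genes) > 5) "...", "\n")
})

setMethod("length", "GeneSignature", function(x) length(x@genes))

#' Write / read a gene signature
#'
#' Signatures are stored as two-column delimited text (gene, importance)
#' with \code{#}-prefixed provenance header lines; the importance column
#' is omitted when no scores are attached. The round trip is exact:
#' \code{readSignature(writeSignature(s, p))} reproduces \code{s}
#' including gene order and importance values.
#'
#' @param sig a \linkS4class{GeneSignature}.
#' @param path file path (\code{.csv} = comma-delimited, otherwise tab).
#' @return \code{writeSignature} invisibly returns \code{path};
#'   \code{readSignature} returns a \linkS4class{GeneSignature}.
#' @export
writeSignature <- function(sig, path) {
  sep <- .delim_for(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# name: ", sig@name),
               paste0("# provenance: ", sig@provenance)), con)
  has_imp <- length(sig@importance) > 0
  writeLines(paste(c("gene", if (has_imp) "importance"), collapse = sep), con)
  if (length(sig@genes)) {
    rows <- if (has_imp)
      paste(sig@genes, format(sig@importance, digits = 17, trim = TRUE,
                              scientific = FALSE), sep = sep)
    else sig@genes
    writeLines(rows, con)
  }
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  name <- sub("^# name: ?", "", grep("^# name:", lines, value = TRUE)[1])
  prov <- sub("^# provenance: ?", "", grep("^# provenance:", lines, value = TRUE)[1])
  if (is.na(name)) name <- ""
  if (is.na(prov)) prov <- ""
  body <- lines[!is_header]
  if (!length(body)) stop("malformed signature file (no column header): ", path)
  sep <- .delim_for(path)
  cols <- strsplit(body[1], sep, fixed = TRUE)[[1]]
  if (!identical(cols[1], "gene"))
    stop("malformed signature file at line ", which(!is_header)[1],
         ": expected 'gene' column header")
  has_imp <- length(cols) >= 2 && cols[2] == "importance"
  genes <- character(0); imp <- numeric(0)
  for (i in seq_along(body)[-1]) {
    parts <- strsplit(body[i], sep, fixed = TRUE)[[1]]
    if (length(parts) < 1 + has_imp || !nzchar(parts[1]))
      stop("malformed signature file at line ", which(!is_header)[i], ": ", body[i])
    genes <- c(genes, parts[1])
    if (has_imp) {
      v <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(v))
        stop("malformed importance value at line ", which(!is_header)[i], ": ", body[i])
      imp <- c(imp, v)
    }
  }
  if (anyDuplicated(genes))
    stop("duplicate genes in signature file: ",
         paste(.dup_names(genes), collapse = ", "))
  GeneSignature(genes, imp, name = name, provenance = prov)
}

#' @describeIn ClassificationResult-class per-sample probability scores
#'   (named numeric).
#' @param result a \linkS4class{ClassificationResult}.
#' @export
probScores <- function(result) setNames(result@prob_score, result@sample_ids)

#' @describeIn ClassificationResult-class per-sample predicted labels
#'   (named character).
#' @export
predictedLabels <- function(result) setNames(result@predicted_label, result@sample_ids)

setMethod("show", "ClassificationResult", function(object) {
  pos <- object@class_order[2]
  cat("ClassificationResult:", length(object@sample_ids), "samples;",
      sum(object@predicted_label == pos), "called", pos,
      sprintf("(threshold > %.3g)\n", object@threshold))
})
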