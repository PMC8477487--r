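#' Read a nearest-centroid subtype panel
#'
#' The panel file is delimited text: \code{#}-prefixed header lines carry
#' the ROR (risk-of-recurrence) coefficients and affine scaling
#' constants, followed by a gene-by-subtype centroid matrix with a
#' \code{gene} id column and one column per subtype. Header keys:
#' \code{# ror_coefficients: <subtype>=<value>,...},
#' \code{# ror_intercept: <value>}, \code{# ror_scale: <value>}.
#'
#' A 10-gene synthetic demonstration panel ships with the package
#' (\code{system.file("extdata", "synthetic_pam50_panel.tsv",
#' package = "ibcsig")}); any centroid/coefficient set in this format —
#' e.g. a real 50-gene panel — can be supplied instead.
#'
#' @param path panel file path.
#' @return a \linkS4class{CentroidPanel}.
#' @export
readCentroidPanel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_hdr <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (!length(ln)) stop("panel file missing '# ", key, ":' header")
    sub(paste0("^# ", key, ": "), "", ln[1])
  }
  co_raw <- strsplit(get_hdr("ror_coefficients"), ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(co_raw), "=", fixed = TRUE)
  coefs <- setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                    vapply(kv, `[`, character(1), 1))
  body <- lines[!grepl("^#", lines)]
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    sep = .delim_for(path), check.names = FALSE)
  centroids <- as.matrix(tab[, -1, drop = FALSE])
  rownames(centroids) <- tab[[1]]
  new("CentroidPanel", genes = tab[[1]], centroids = centroids,
      ror_coefficients = coefs,
      ror_intercept = as.numeric(get_hdr("ror_intercept")),
      ror_scale = as.numeric(get_hdr("ror_scale")))
}

#' Nearest-centroid intrinsic-subtype calls
#'
#' For each sample, computes the Spearman rank correlation between its
#' panel-gene expression and each subtype centroid; the call is the
#' argmax-correlation subtype (ties broken deterministically by the
#' panel's subtype column order). Rank correlation makes the calls
#' invariant to any monotone per-sample transformation of expression.
#' Panel genes missing from the cohort are dropped with a warning; below
#' 50\% panel coverage the call is refused with a coverage report.
#' The risk-of-recurrence score is attached via [rorScore()].
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param panel a \linkS4class{CentroidPanel}.
#' @param method correlation type (default \code{"spearman"}).
#' @return a \linkS4class{SubtypeCall}.
#' @export
pam50Call <- function(cohort, panel, method = "spearman") {
  present <- intersect(panel@genes, rownames(cohort))
  missing_genes <- setdiff(panel@genes, rownames(cohort))
  coverage <- length(present) / length(panel@genes)
  if (coverage < 0.5)
    stop(sprintf(
      "panel coverage %.0f%% (< 50%%): %d of %d panel genes missing: %s",
      100 * coverage, length(missing_genes), length(panel@genes),
      paste(missing_genes, collapse = ", ")))
  if (length(missing_genes))
    warning(length(missing_genes), " panel gene(s) missing from cohort: ",
            paste(missing_genes, collapse = ", "))
  x <- exprValues(cohort)[present, , drop = FALSE]
  centroids <- panel@centroids[present, , drop = FALSE]
  cors <- cor(x, centroids, method = method)  # samples x subtypes
  subtype <- colnames(cors)[max.col(cors, ties.method = "first")]
  call <- new("SubtypeCall", sample_ids = colnames(cohort),
              subtype = subtype, correlations = cors,
              ror_score = rep(NA_real_, ncol(cohort)))
  call@ror_score <- rorScore(call, panel)
  call
}

#' Risk-of-recurrence (ROR) score
#'
#' A linear combination of the per-subtype centroid correlations with the
#' panel's ROR coefficients, affinely rescaled by the panel's constants:
#' \deqn{ROR = intercept + scale \cdot \sum_s coef_s \, \rho_s.}
#'
#' @param call a \linkS4class{SubtypeCall}.
#' @param panel the \linkS4class{CentroidPanel} supplying coefficients.
#' @return named numeric, one score per sample.
#' @export
rorScore <- function(call, panel) {
  coefs <- panel@ror_coefficients
  if (any(is.na(coefs))) stop("panel ROR coefficients contain missing values")
  subtypes <- colnames(call@correlations)
  if (!all(subtypes %in% names(coefs)))
    stop("missing ROR coefficient for subtype(s): ",
         paste(setdiff(subtypes, names(coefs)), collapse = ", "))
  raw <- as.vector(call@correlations %*% coefs[subtypes])
  setNames(panel@ror_intercept + panel@ror_scale * raw, call@sample_ids)
}

#' @describeIn pam50Call per-sample subtype labels (named character).
#' @param call a \linkS4class{SubtypeCall}.
#' @export
subtypeLabels <- function(call) setNames(call@subtype, call@sample_ids)

#' @describeIn pam50Call samples-by-subtype correlation matrix.
#' @export
subtypeCorrelations <- function(call) call@correlations

setMethod("show", "SubtypeCall", function(object) {
  tab <- table(object@subtype)
  cat("SubtypeCall:", length(object@sample_ids), "samples;",
      paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
})
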