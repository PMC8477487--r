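#' Calinski-Harabasz cluster-validity index
#'
#' \deqn{CH(k) = \frac{B/(k-1)}{W/(n-k)}}
#' where \eqn{B} is the between-cluster and \eqn{W} the within-cluster
#' sum of squared Euclidean distances to the respective centroids.
#' Degenerate partitions — a single cluster, \eqn{k = n}, or zero
#' within-cluster dispersion — return \code{NA} rather than an infinite
#' value.
#'
#' @param x samples-by-features numeric matrix.
#' @param labels cluster assignment, one per row of \code{x}.
#' @return the index value, or \code{NA} when undefined.
#' @export
chIndex <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  labels <- as.character(labels)
  ks <- unique(labels)
  k <- length(ks)
  if (k < 2 || k >= n) return(NA_real_)
  grand <- colMeans(x)
  W <- 0; B <- 0
  for (cl in ks) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    W <- W + sum(sweep(xi, 2, ci)^2)
    B <- B + nrow(xi) * sum((ci - grand)^2)
  }
  if (W <= .Machine$double.eps * max(1, B)) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

.zscore_genes <- function(m) {
  s <- apply(m, 1, sd)
  s[s == 0] <- 1
  (m - rowMeans(m)) / s
}

#' Hierarchical clustering of samples on signature genes
#'
#' Agglomeratively clusters the cohort's samples on the expression of the
#' signature genes, cuts the tree into k = 2..\code{k_max} flat
#' partitions, and scores each with the Calinski-Harabasz index; the
#' optimal cluster number is the argmax. By default genes are z-scored
#' before the Euclidean distance is taken and average linkage is used —
#' the standard display space for expression heatmaps; both are exposed.
#' The clustering is label-blind: annotations play no role.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with at least 3
#'   samples.
#' @param sig a \linkS4class{GeneSignature}; its genes must be present.
#' @param k_max largest cluster number scored (default 8; must be below
#'   the sample count).
#' @param linkage \code{hclust} agglomeration method (default
#'   \code{"average"}).
#' @param distance \code{dist} metric (default \code{"euclidean"}).
#' @param scale_genes z-score each gene before clustering (default TRUE).
#' @return a \linkS4class{ClusteringResult}.
#' @export
hierCluster <- function(cohort, sig, k_max = 8, linkage = "average",
                        distance = "euclidean", scale_genes = TRUE) {
  if (ncol(cohort) < 3) stop("need at least 3 samples")
  if (k_max >= ncol(cohort))
    stop("k_max must be smaller than the number of samples")
  missing_genes <- setdiff(sigGenes(sig), rownames(cohort))
  if (length(missing_genes))
    stop("signature gene(s) missing from cohort: ",
         paste(missing_genes, collapse = ", "))
  m <- exprValues(cohort)[sigGenes(sig), , drop = FALSE]
  if (scale_genes) m <- .zscore_genes(m)
  x <- t(m)
  hc <- hclust(dist(x, method = distance), method = linkage)
  ks <- 2:k_max
  labels <- vapply(ks, function(k) cutree(hc, k = k), integer(nrow(x)))
  dimnames(labels) <- list(rownames(x), paste0("k", ks))
  ch <- setNames(vapply(seq_along(ks), function(i) chIndex(x, labels[, i]),
                        numeric(1)), paste0("k", ks))
  opt <- if (all(is.na(ch))) NA_integer_ else ks[which.max(ch)]
  new("ClusteringResult", hclust = hc, labels = labels, ch_scores = ch,
      optimal_k = as.integer(opt))
}

#' @describeIn hierCluster the optimal cluster number (argmax CH).
#' @param result a \linkS4class{ClusteringResult}.
#' @export
optimalK <- function(result) result@optimal_k

#' @describeIn hierCluster the per-k Calinski-Harabasz scores.
#' @export
chScores <- function(result) result@ch_scores

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult:", nrow(object@labels), "samples, k =",
      paste(range(2, ncol(object@labels) + 1), collapse = ".."),
      "; optimal k =", object@optimal_k, "\n")
})

#' Principal-component projection of samples on signature genes
#'
#' Mean-centered PCA of the samples in signature-gene space. The sign of
#' each component is fixed by making its largest-magnitude gene loading
#' positive, so projections are deterministic and invariant to gene
#' order. Label-blind: annotations play no role.
#'
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param sig a \linkS4class{GeneSignature}; its genes must be present.
#' @param m number of components (at most
#'   \code{min(n_samples - 1, n_genes)}).
#' @return a \linkS4class{PcaProjection}.
#' @export
pcaProject <- function(cohort, sig, m = 2) {
  missing_genes <- setdiff(sigGenes(sig), rownames(cohort))
  if (length(missing_genes))
    stop("signature gene(s) missing from cohort: ",
         paste(missing_genes, collapse = ", "))
  x <- t(exprValues(cohort)[sigGenes(sig), , drop = FALSE])
  m_max <- min(nrow(x) - 1, ncol(x))
  if (m > m_max)
    stop("m = ", m, " components requested but at most ", m_max,
         " are available")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  # deterministic sign: largest-|loading| gene positive per component
  for (j in seq_len(m)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaProjection", coordinates = pc$x[, seq_len(m), drop = FALSE],
      explained_variance = ev[seq_len(m)])
}

#' @describeIn pcaProject sample coordinates on the components.
#' @param projection a \linkS4class{PcaProjection}.
#' @export
pcaCoordinates <- function(projection) projection@coordinates

#' @describeIn pcaProject explained-variance fractions.
#' @export
explainedVariance <- function(projection) projection@explained_variance

setMethod("show", "PcaProjection", function(object) {
  cat("PcaProjection:", nrow(object@coordinates), "samples x",
      ncol(object@coordinates), "components;",
      "explained:", paste(sprintf("%.1f%%", 100 * object@explained_variance),
                          collapse = ", "), "\n")
})
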