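## Count cleaning, expression filters and TMM normalization. The fixed
## filter order is clean -> CPM -> CV -> TMM -> connectivity; each step is
## idempotent on its own output and never touches the sample set.

#' Remove unusable genes
#'
#' Drops genes with any missing value and genes with zero counts in every
#' sample. Samples are untouched.
#'
#' @param counts Count matrix, genes x samples.
#' @return Filtered count matrix.
#' @export
cleanGenes <- function(counts) {
  counts <- as.matrix(counts)
  keep <- !apply(counts, 1, anyNA) &
    apply(counts, 1, function(r) any(r != 0, na.rm = TRUE))
  if (!any(keep)) stop("all genes removed")
  counts[keep, , drop = FALSE]
}

## CPM on raw library sizes (column sums).
cpmMatrix <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("nonpositive library size")
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter low-expression genes by mean CPM
#'
#' Removes genes whose mean counts-per-million across samples falls below
#' the threshold (strict \code{<}; a gene at exactly the threshold is
#' retained).
#'
#' @param counts Count matrix, genes x samples.
#' @param threshold Mean-CPM cutoff (default 0.5).
#' @return Filtered count matrix.
#' @export
cpmFilter <- function(counts, threshold = 0.5) {
  counts <- as.matrix(counts)
  keep <- rowMeans(cpmMatrix(counts)) >= threshold
  counts[keep, , drop = FALSE]
}

#' Drop the least-variable quartile of genes
#'
#' Computes each gene's coefficient of variation (sd/mean on the CPM
#' scale) and removes the lowest quartile, retaining
#' \code{ceiling(0.75 * nrow)} genes. Ties are broken deterministically by
#' ascending gene identifier: among tied CVs, alphabetically earlier genes
#' are removed first.
#'
#' @param counts Count matrix with >= 4 genes, no zero-mean gene.
#' @return Filtered count matrix.
#' @export
cvFilter <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4) stop("cvFilter needs at least 4 genes")
  cpm <- cpmMatrix(counts)
  mu <- rowMeans(cpm)
  if (any(mu == 0)) stop("zero-mean gene present; run cleanGenes first")
  cv <- apply(cpm, 1, sd) / mu
  keep <- ceiling(0.75 * nrow(counts))
  ord <- order(cv, rownames(counts))  # ascending CV, then identifier
  counts[sort(ord[seq.int(nrow(counts) - keep + 1, nrow(counts))]), ,
         drop = FALSE]
}

#' TMM-normalize counts to log2 CPM
#'
#' Computes trimmed-mean-of-M-values scaling factors (30\% M-trim, 5\%
#' A-trim, reference = sample whose upper quartile is closest to the mean
#' upper quartile; factors geometric-mean-normalized to 1) and returns
#' \code{log2(CPM + 1)} on effective library sizes. The scaling factors
#' are attached as attribute \code{"norm.factors"}.
#'
#' @param counts Cleaned count matrix.
#' @return Numeric matrix of log2(CPM+1) values with a
#'   \code{norm.factors} attribute.
#' @export
tmmNormalize <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("sample with zero library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  eff <- lib * f
  expr <- log2(sweep(counts, 2, eff, "/") * 1e6 + 1)
  attr(expr, "norm.factors") <- f
  expr
}

#' Scaled connectivity of a gene
#'
#' Connectivity is the sum of a gene's absolute correlations to all other
#' genes, divided by (G - 1) so it lies in [0, 1] regardless of network
#' size.
#'
#' @param network A \linkS4class{CoexpressionNetwork}.
#' @param gene Gene identifier.
#' @return Scaled connectivity in [0, 1].
#' @export
connectivity <- function(network, gene) {
  a <- abs(network@adjacency)
  if (!gene %in% rownames(a)) stop("gene not in network: ", gene)
  (sum(a[gene, ]) - 1) / (nrow(a) - 1)
}

## Scaled connectivity of every gene at once.
connectivityAll <- function(network) {
  a <- abs(network@adjacency)
  (rowSums(a) - 1) / (nrow(a) - 1)
}

#' Remove weakly connected genes
#'
#' Computes the pooled-condition correlation network over all samples and
#' drops genes whose scaled connectivity falls below the threshold.
#'
#' @param expr Normalized expression matrix (genes x samples), >= 3 genes.
#' @param threshold Scaled-connectivity cutoff (default 0.1).
#' @return Filtered expression matrix.
#' @export
connectivityFilter <- function(expr, threshold = 0.1) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) stop("connectivityFilter needs at least 3 genes")
  net <- correlationNetwork(expr, colnames(expr), condition = "pooled")
  k <- connectivityAll(net)
  expr[k >= threshold, , drop = FALSE]
}

#' Run the full preprocessing chain
#'
#' clean -> mean-CPM filter -> CV-quartile filter -> TMM normalization ->
#' connectivity filter, recording per-step gene counts.
#'
#' @param se A \linkS4class{StageExperiment} with a \code{counts} assay.
#' @param cpmThreshold,connectivityThreshold Filter cutoffs.
#' @return A \linkS4class{StageExperiment} restricted to surviving genes
#'   with an added \code{logcpm} assay; the per-step report is in
#'   \code{metadata(se)$filterReport}.
#' @export
preprocessCounts <- function(se, cpmThreshold = 0.5,
                             connectivityThreshold = 0.1) {
  counts <- SummarizedExperiment::assay(se, "counts")
  report <- c(input = nrow(counts))
  counts <- cleanGenes(counts);           report["clean"] <- nrow(counts)
  counts <- cpmFilter(counts, cpmThreshold); report["cpm"] <- nrow(counts)
  counts <- cvFilter(counts);             report["cv"] <- nrow(counts)
  expr <- tmmNormalize(counts)
  expr <- connectivityFilter(expr, connectivityThreshold)
  report["connectivity"] <- nrow(expr)
  out <- se[rownames(expr), ]
  SummarizedExperiment::assay(out, "logcpm", withDimnames = FALSE) <-
    expr[, colnames(out), drop = FALSE]
  S4Vectors::metadata(out)$filterReport <- report
  S4Vectors::metadata(out)$normFactors <- attr(expr, "norm.factors")
  methods::validObject(out)
  out
}
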