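#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom stats cor median quantile sd rnorm rpois runif rexp
#'   p.adjust pchisq pnorm hclust as.dist cutree fisher.test kruskal.test
#'   shapiro.test t.test lm coef predict var setNames
NULL

#' Multi-stage expression experiment
#'
#' A \linkS4class{SummarizedExperiment} whose columns are samples annotated
#' with a progression condition (\code{normal}, \code{I}--\code{IV}) and,
#' optionally, overall-survival follow-up (\code{time}, \code{event}); rows
#' are genes optionally annotated with \code{coding},
#' \code{diseaseAssociated} and \code{ncCancerReported} flags. The
#' \code{"counts"} assay holds raw non-negative integer counts; downstream
#' steps add a \code{"logcpm"} assay of normalized expression.
#'
#' @slot .. inherited from \code{SummarizedExperiment}.
#' @seealso [StageExperiment()] for the constructor.
#' @export
setClass("StageExperiment", contains = "SummarizedExperiment")

setValidity("StageExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if (!"condition" %in% colnames(cd))
    return("colData must contain a 'condition' column")
  cond <- as.character(cd$condition)
  bad <- setdiff(unique(cond), CONDITION_LEVELS)
  if (length(bad))
    return(paste0("unknown condition label(s): ", paste(bad, collapse = ", ")))
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("a 'counts' assay is required")
  if (anyDuplicated(rownames(object)))
    return("gene identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    return("sample identifiers must be unique")
  TRUE
})

#' Per-condition co-expression network
#'
#' Symmetric signed Pearson-correlation adjacency over a gene set, computed
#' from the samples of one condition (or pool of conditions).
#'
#' @slot adjacency Symmetric numeric matrix of Pearson r, diagonal 1,
#'   dimnames = gene identifiers.
#' @slot nSamples Number of samples the correlations were estimated from.
#' @slot condition Label of the sample group ("pooled" when unrestricted).
#' @export
setClass("CoexpressionNetwork",
  representation(adjacency = "matrix", nSamples = "integer",
                 condition = "character"))

setValidity("CoexpressionNetwork", function(object) {
  a <- object@adjacency
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    return("adjacency needs identical row/column gene names")
  if (!isSymmetricMat(a)) return("adjacency must be symmetric")
  if (max(abs(a)) > 1 + 1e-8) return("correlations must lie in [-1, 1]")
  if (max(abs(diag(a) - 1)) > 1e-8) return("diagonal must be 1")
  TRUE
})

#' Differential co-expression dissimilarity
#'
#' Symmetric gene-gene dissimilarity contrasting the correlation structure
#' of two sample groups (DiffCoEx-style), optionally passed through a
#' topological-overlap transform. Entries lie in [0, 1], diagonal 0.
#'
#' @slot dissimilarity Symmetric numeric matrix in [0, 1], diagonal 0.
#' @slot beta Even positive soft-threshold exponent.
#' @slot useTom Whether the topological-overlap transform was applied.
#' @slot conditions Length-2 labels of the contrasted groups.
#' @export
setClass("DiffMatrix",
  representation(dissimilarity = "matrix", beta = "integer",
                 useTom = "logical", conditions = "character"))

setValidity("DiffMatrix", function(object) {
  d <- object@dissimilarity
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("dissimilarity needs identical row/column gene names")
  if (!isSymmetricMat(d)) return("dissimilarity must be symmetric")
  if (min(d) < -1e-10 || max(d) > 1 + 1e-10)
    return("entries must lie in [0, 1]")
  if (max(abs(diag(d))) > 1e-10) return("diagonal must be 0")
  if (length(object@beta) != 1L || object@beta < 2L || object@beta %% 2L != 0L)
    return("beta must be a positive even integer")
  TRUE
})

#' Gene-to-module assignment
#'
#' Named character vector mapping each gene to a module label. Labels are
#' \code{"module_1"}, \code{"module_2"}, ... ordered by decreasing module
#' size; genes in no module carry \code{"unassigned"}.
#'
#' @slot labels Named character vector, names = genes.
#' @export
setClass("ModulePartition", representation(labels = "character"))

setValidity("ModulePartition", function(object) {
  lab <- object@labels
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    return("labels must be named by unique gene identifiers")
  mods <- setdiff(unique(lab), "unassigned")
  if (length(mods)) {
    expect <- paste0("module_", seq_along(mods))
    if (!setequal(mods, expect))
      return("module labels must be module_1..module_k")
    sz <- as.integer(table(factor(lab, levels = expect)))
    if (is.unsorted(rev(sz)))
      return("module_k must be at least as large as module_{k+1}")
  }
  TRUE
})

#' Module preservation statistics
#'
#' Per-module permutation-based preservation summary between a reference
#' and a test network: density and connectivity statistics, their
#' permutation Z-scores, the composite \code{Zsummary} and the
#' \code{Medianrank} across modules, plus the permuted Zsummary draws used
#' for the non-randomness test.
#'
#' @slot stats data.frame with one row per scored module.
#' @slot permZsummary matrix (nPerm x modules) of permuted Zsummary values.
#' @slot nPerm Number of label permutations used.
#' @slot seed Seed the permutations were drawn under.
#' @export
setClass("PreservationResult",
  representation(stats = "data.frame", permZsummary = "matrix",
                 nPerm = "integer", seed = "integer"))

setValidity("PreservationResult", function(object) {
  need <- c("module", "meanCor", "meanAdj", "corKIM", "corCor",
            "Zdensity", "Zconnectivity", "Zsummary", "Medianrank")
  if (!all(need %in% colnames(object@stats)))
    return(paste("stats must contain:", paste(need, collapse = ", ")))
  mr <- object@stats$Medianrank
  if (length(mr) && (min(mr) < 1 || max(mr) > nrow(object@stats)))
    return("Medianrank must lie in [1, number of modules]")
  TRUE
})

#' Fitted proportional-hazards risk model
#'
#' Cox model over selected gene covariates with per-patient risk scores
#' \eqn{\exp(\beta' x)}, quartile strata thresholds on the fitting cohort,
#' likelihood-ratio p-value and Harrell's concordance.
#'
#' @slot covariates Gene identifiers entering the model.
#' @slot coefficients Named log-hazard coefficients.
#' @slot hazardRatios \code{exp(coefficients)}.
#' @slot lrTestP Global likelihood-ratio test p-value.
#' @slot cIndex Harrell's c-index on the fitting cohort.
#' @slot strataThresholds Q1 and Q3 of the fitting cohort's risk scores.
#' @slot fit The underlying \code{survival::coxph} fit.
#' @export
setClass("RiskModel",
  representation(covariates = "character", coefficients = "numeric",
                 hazardRatios = "numeric", lrTestP = "numeric",
                 cIndex = "numeric", strataThresholds = "numeric",
                 fit = "ANY"))

setValidity("RiskModel", function(object) {
  if (!isTRUE(all.equal(unname(object@hazardRatios),
                        unname(exp(object@coefficients)))))
    return("hazardRatios must equal exp(coefficients)")
  q <- object@strataThresholds
  if (length(q) != 2L || q[1] > q[2])
    return("strataThresholds must be (Q1, Q3) with Q1 <= Q3")
  TRUE
})

#' Correlation network thresholded at a cutoff
#'
#' Edge list of gene pairs whose Pearson correlation magnitude reaches the
#' cutoff within one condition's samples; signs are retained.
#'
#' @slot condition Condition the network was computed in.
#' @slot edges data.frame(geneA, geneB, r), unordered pairs, no self-edges.
#' @slot genes Gene universe the network was computed over.
#' @slot cutoff Absolute-correlation threshold for edge presence.
#' @export
setClass("ThresholdedNetwork",
  representation(condition = "character", edges = "data.frame",
                 genes = "character", cutoff = "numeric"))

setValidity("ThresholdedNetwork", function(object) {
  e <- object@edges
  if (!all(c("geneA", "geneB", "r") %in% colnames(e)))
    return("edges must have columns geneA, geneB, r")
  if (nrow(e)) {
    if (any(e$geneA == e$geneB)) return("self-edges are not allowed")
    if (any(e$geneA >= e$geneB))
      return("edges must be stored with geneA < geneB")
    if (min(abs(e$r)) < object@cutoff - 1e-12)
      return("every stored edge must satisfy |r| >= cutoff")
  }
  TRUE
})

#' Re-wired edges between two consecutive conditions
#'
#' Gained, lost and sign-reversed edges between the thresholded networks of
#' an earlier and a later condition, with the hub genes of the change set.
#'
#' @slot transition Length-2 (earlier, later) condition labels, adjacent in
#'   the order normal, I, II, III, IV.
#' @slot edges data.frame(geneA, geneB, class, rEarlier, rLater), class in
#'   gain/loss/reversed.
#' @slot hubs Genes with the most changed incident edges.
#' @slot cutoff Edge-presence cutoff shared by the two networks.
#' @export
setClass("RewiringEdgeSet",
  representation(transition = "character", edges = "data.frame",
                 hubs = "character", cutoff = "numeric"))

setValidity("RewiringEdgeSet", function(object) {
  tr <- object@transition
  if (length(tr) != 2L) return("transition must name two conditions")
  i <- match(tr, CONDITION_LEVELS)
  if (anyNA(i)) return("unknown condition in transition")
  ## adjacent in progression order; a self-comparison (always empty by
  ## construction) is also permitted
  if (!(i[2] - i[1]) %in% c(0L, 1L))
    return("transition conditions must be consecutive (normal->I->..->IV)")
  e <- object@edges
  need <- c("geneA", "geneB", "class", "rEarlier", "rLater")
  if (!all(need %in% colnames(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) && !all(e$class %in% c("gain", "loss", "reversed")))
    return("edge class must be gain, loss or reversed")
  TRUE
})
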