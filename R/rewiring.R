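## Per-condition thresholded networks over the prognostic gene set, edge
## change classification between consecutive conditions, hub extraction
## and the five-index progression-biomarker ranking.

#' Thresholded correlation network for one condition
#'
#' Pearson correlations over the condition's samples; pairs with
#' \code{|r| >= cutoff} become edges (signs retained, boundary
#' inclusive). Genes with zero variance in the condition are excluded
#' with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param samples Samples of the condition (>= 3).
#' @param genes Gene set to restrict to (>= 2).
#' @param condition Condition label.
#' @param cutoff Absolute-correlation threshold (default 0.7).
#' @return A \linkS4class{ThresholdedNetwork}.
#' @export
conditionNetwork <- function(expr, samples, genes,
                             condition = "pooled", cutoff = 0.7) {
  if (length(samples) < 3) stop("need at least 3 samples")
  if (length(genes) < 2) stop("need at least 2 genes")
  sub <- expr[genes, samples, drop = FALSE]
  v <- apply(sub, 1, var)
  if (any(v == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    sub <- sub[v > 0, , drop = FALSE]
    genes <- rownames(sub)
  }
  r <- cor(t(sub))
  idx <- which(upper.tri(r) & abs(r) >= cutoff, arr.ind = TRUE)
  edges <- data.frame(geneA = rownames(r)[idx[, 1]],
                      geneB = colnames(r)[idx[, 2]],
                      r = r[idx], row.names = NULL)
  swap <- edges$geneA > edges$geneB
  tmp <- edges$geneA[swap]
  edges$geneA[swap] <- edges$geneB[swap]
  edges$geneB[swap] <- tmp
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  methods::new("ThresholdedNetwork", condition = condition,
               edges = edges, genes = genes, cutoff = cutoff)
}

#' Classify re-wired edges between two consecutive conditions
#'
#' An edge (|r| above the cutoff) present only in the later network is a
#' \emph{gain}, present only in the earlier a \emph{loss}, and present in
#' both with opposite correlation signs \emph{reversed}; unchanged edges
#' are omitted. Hubs of the change set are attached via [hubNodes()].
#'
#' @param earlier,later \linkS4class{ThresholdedNetwork}s with the same
#'   gene universe and cutoff.
#' @param topFraction Hub fraction passed to [hubNodes()].
#' @return A \linkS4class{RewiringEdgeSet}.
#' @export
classifyRewiring <- function(earlier, later, topFraction = 0.1) {
  if (earlier@cutoff != later@cutoff)
    stop("the two networks must share the same cutoff")
  key <- function(e) paste(e$geneA, e$geneB, sep = "\r")
  eE <- earlier@edges; eL <- later@edges
  kE <- key(eE); kL <- key(eL)
  lost <- eE[!kE %in% kL, , drop = FALSE]
  gained <- eL[!kL %in% kE, , drop = FALSE]
  common <- intersect(kE, kL)
  iE <- match(common, kE); iL <- match(common, kL)
  rev_ <- sign(eE$r[iE]) != sign(eL$r[iL])
  edges <- rbind(
    if (nrow(gained)) data.frame(geneA = gained$geneA,
                                 geneB = gained$geneB, class = "gain",
                                 rEarlier = NA_real_, rLater = gained$r),
    if (nrow(lost)) data.frame(geneA = lost$geneA, geneB = lost$geneB,
                               class = "loss", rEarlier = lost$r,
                               rLater = NA_real_),
    if (any(rev_)) data.frame(geneA = eE$geneA[iE][rev_],
                              geneB = eE$geneB[iE][rev_],
                              class = "reversed",
                              rEarlier = eE$r[iE][rev_],
                              rLater = eL$r[iL][rev_]))
  if (is.null(edges))
    edges <- data.frame(geneA = character(0), geneB = character(0),
                        class = character(0), rEarlier = numeric(0),
                        rLater = numeric(0))
  edges <- edges[order(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  out <- methods::new("RewiringEdgeSet",
                      transition = c(earlier@condition, later@condition),
                      edges = edges, hubs = character(0),
                      cutoff = earlier@cutoff)
  if (nrow(edges)) out@hubs <- hubNodes(out, topFraction)
  out
}

#' Hub genes of a re-wiring change set
#'
#' Genes ranked by the number of changed incident edges; hubs are the top
#' \code{ceiling(topFraction * g)} of the \code{g} genes with at least
#' one changed edge (minimum 1), ties broken by gene-identifier order.
#'
#' @param changes A \linkS4class{RewiringEdgeSet} with >= 1 changed edge.
#' @param topFraction Fraction of changed genes reported (default 0.1).
#' @return Character vector of hub genes.
#' @export
hubNodes <- function(changes, topFraction = 0.1) {
  e <- changes@edges
  if (!nrow(e)) stop("no changed edge to rank")
  deg <- sort(table(c(e$geneA, e$geneB)), decreasing = TRUE)
  ## stable ordering: degree descending, then gene identifier
  nm <- names(deg)[order(-as.integer(deg), names(deg))]
  nHub <- max(1L, ceiling(topFraction * length(nm)))
  nm[seq_len(nHub)]
}

#' Rank progression biomarkers by five indices
#'
#' Each gene is scored on five booleans — prognostic, monotone
#' (ascending/descending) stage trend, hub in at least one transition,
#' novel, and re-wired in at least one transition — and ranked by the
#' number of satisfied indices; ties are broken by the number of
#' transitions with re-wiring, then by gene identifier.
#'
#' @param genes Gene identifiers.
#' @param prognostic Logical per gene.
#' @param trendClass Character per gene (from [classifyTrends()]).
#' @param hubTransitions Integer per gene: transitions in which the gene
#'   is a hub.
#' @param novel Logical per gene (externally supplied novelty flag).
#' @param rewiredTransitions Integer per gene: transitions in which any
#'   incident edge changed.
#' @return data.frame ordered by rank with the five index columns,
#'   \code{nIndices} and \code{rank}.
#' @export
rankProgressionBiomarkers <- function(genes, prognostic, trendClass,
                                      hubTransitions, novel,
                                      rewiredTransitions) {
  stopifnot(length(prognostic) == length(genes),
            length(trendClass) == length(genes),
            length(hubTransitions) == length(genes),
            length(novel) == length(genes),
            length(rewiredTransitions) == length(genes))
  idx <- data.frame(
    gene = genes,
    prognostic = as.logical(prognostic),
    trend = trendClass %in% c("ascending", "descending"),
    hub = hubTransitions >= 1,
    novel = as.logical(novel),
    rewired = rewiredTransitions >= 1,
    rewiredTransitions = as.integer(rewiredTransitions))
  idx$nIndices <- rowSums(idx[, c("prognostic", "trend", "hub", "novel",
                                  "rewired")])
  ord <- order(-idx$nIndices, -idx$rewiredTransitions, idx$gene)
  idx <- idx[ord, , drop = FALSE]
  idx$rank <- seq_len(nrow(idx))
  rownames(idx) <- NULL
  idx
}
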