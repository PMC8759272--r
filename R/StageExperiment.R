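#' Construct a StageExperiment
#'
#' Bundle a gene x sample count matrix with per-sample condition labels,
#' optional survival follow-up and optional per-gene annotation into a
#' \linkS4class{StageExperiment}.
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param condition Character/factor of length \code{ncol(counts)} with
#'   values in \code{normal, I, II, III, IV}.
#' @param time,event Optional numeric survival time (> 0) and 0/1 event
#'   indicator per sample.
#' @param annotation Optional data.frame with columns \code{gene},
#'   \code{coding}, \code{diseaseAssociated}, \code{ncCancerReported}
#'   (as produced by [simulateAnnotations()]).
#' @return A \linkS4class{StageExperiment}.
#' @examples
#' cfg <- simulationConfig(seed = 1L)
#' sim <- simulateStageData(cfg)
#' se <- StageExperiment(sim$counts, sim$design$condition)
#' se
#' @export
StageExperiment <- function(counts, condition, time = NULL, event = NULL,
                            annotation = NULL) {
  counts <- as.matrix(counts)
  cond <- checkConditions(condition)
  if (length(cond) != ncol(counts))
    stop("condition must have one entry per sample column")
  cd <- S4Vectors::DataFrame(condition = cond, row.names = colnames(counts))
  if (!is.null(time)) cd$time <- as.numeric(time)
  if (!is.null(event)) cd$event <- as.integer(event)
  rd <- S4Vectors::DataFrame(row.names = rownames(counts))
  if (!is.null(annotation)) {
    i <- match(rownames(counts), annotation$gene)
    if (anyNA(i)) stop("annotation is missing some genes of the count matrix")
    rd$coding <- annotation$coding[i]
    rd$diseaseAssociated <- annotation$diseaseAssociated[i]
    rd$ncCancerReported <- annotation$ncCancerReported[i]
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  methods::new("StageExperiment", se)
}

#' @describeIn StageExperiment Condition factor of the samples.
#' @param x A StageExperiment.
#' @export
stageConditions <- function(x) {
  factor(as.character(SummarizedExperiment::colData(x)$condition),
         levels = CONDITION_LEVELS)
}

#' @describeIn StageExperiment Sample identifiers of one condition.
#' @param cond A single condition label.
#' @export
samplesOf <- function(x, cond) {
  colnames(x)[as.character(stageConditions(x)) == cond]
}

#' @describeIn StageExperiment Survival data.frame (sample, time, event),
#'   or error when the experiment carries no follow-up.
#' @export
survivalData <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("time", "event") %in% colnames(cd)))
    stop("StageExperiment carries no survival columns")
  data.frame(sample = colnames(x), time = cd$time, event = cd$event,
             row.names = NULL)
}

setMethod("show", "StageExperiment", function(object) {
  cat("StageExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  print(table(stageConditions(object)))
  cat("assays:", paste(SummarizedExperiment::assayNames(object),
                       collapse = ", "), "\n")
  cd <- SummarizedExperiment::colData(object)
  if (all(c("time", "event") %in% colnames(cd)))
    cat("survival: ", sum(cd$event), " events / ", nrow(cd), " samples\n",
        sep = "")
})

setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork (", object@condition, "): ",
      nrow(object@adjacency), " genes, n = ", object@nSamples,
      " samples\n", sep = "")
})

setMethod("show", "DiffMatrix", function(object) {
  cat("DiffMatrix [", paste(object@conditions, collapse = " vs "), "]: ",
      nrow(object@dissimilarity), " genes, beta = ", object@beta,
      ", TOM = ", object@useTom, "\n", sep = "")
})

setMethod("show", "ModulePartition", function(object) {
  sz <- moduleSizes(object)
  cat("ModulePartition:", length(object@labels), "genes,",
      length(sz), "modules\n")
  if (length(sz)) print(sz)
  cat("unassigned:", sum(object@labels == "unassigned"), "\n")
})

setMethod("show", "PreservationResult", function(object) {
  cat("PreservationResult (", object@nPerm, " permutations)\n", sep = "")
  print(object@stats[, c("module", "Zsummary", "Medianrank")],
        row.names = FALSE)
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel:", length(object@covariates), "covariates, c-index =",
      round(object@cIndex, 3), "\n")
  cat("LR-test p =", format(object@lrTestP, digits = 3),
      "; risk quartiles (Q1, Q3) =",
      paste(signif(object@strataThresholds, 4), collapse = ", "), "\n")
})

setMethod("show", "ThresholdedNetwork", function(object) {
  cat("ThresholdedNetwork (", object@condition, "): ",
      nrow(object@edges), " edges over ", length(object@genes),
      " genes at |r| >= ", object@cutoff, "\n", sep = "")
})

setMethod("show", "RewiringEdgeSet", function(object) {
  tab <- table(factor(object@edges$class,
                      levels = c("gain", "loss", "reversed")))
  cat("RewiringEdgeSet ", object@transition[1], " -> ",
      object@transition[2], ": gain = ", tab["gain"], ", loss = ",
      tab["loss"], ", reversed = ", tab["reversed"], "\n", sep = "")
  if (length(object@hubs))
    cat("hubs:", paste(object@hubs, collapse = ", "), "\n")
})

#' Module sizes of a partition
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @return Named integer vector of module sizes, decreasing.
#' @export
moduleSizes <- function(partition) {
  lab <- partition@labels
  mods <- setdiff(unique(lab), "unassigned")
  if (!length(mods)) return(integer(0))
  mods <- mods[order(as.integer(sub("module_", "", mods)))]
  setNames(as.integer(table(factor(lab, levels = mods))), mods)
}

#' Genes belonging to one module
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @param module Module label, e.g. \code{"module_1"}.
#' @return Character vector of gene identifiers.
#' @export
moduleGenes <- function(partition, module) {
  names(partition@labels)[partition@labels == module]
}

#' Gene labels of a partition
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @return Named character vector gene -> module label.
#' @export
moduleLabels <- function(partition) partition@labels
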