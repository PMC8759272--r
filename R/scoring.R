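## Composite module prioritisation. Per stage, every module receives a
## stage-specificity score (from the preservation statistics), a
## disease-relation score (Fisher enrichment of disease-associated coding
## genes) and a non-coding relation score (fraction of cancer-reported
## non-coding genes); their sum — bounded in [0, 4] — selects the
## stage-specific disease-related module.

#' Stage-specificity score per module
#'
#' \deqn{SS_j = (1 - rescale(Zsummary_j)) + rescale(Medianrank_j)}
#' with min-max rescaling across the stage's modules (a constant vector
#' rescales to 0.5, so a single-module stage scores 1). Low Zsummary and
#' high Medianrank — the non-preserved, stage-specific corner — give the
#' maximal score of 2.
#'
#' @param result A \linkS4class{PreservationResult} for one stage.
#' @return Named numeric vector in [0, 2], one entry per module.
#' @export
ssScore <- function(result) {
  s <- result@stats
  setNames((1 - rescale01(s$Zsummary)) + rescale01(s$Medianrank),
           s$module)
}

#' Disease-relation enrichment of a module
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 table of
#' module membership x disease association, restricted to the coding
#' genes of the universe (disease-gene lists are protein-coding).
#'
#' @param moduleGenes Genes of the module.
#' @param annotation data.frame as from [simulateAnnotations()].
#' @param universe All genes surviving preprocessing.
#' @return List with \code{p} (enrichment p-value) and the 2x2
#'   \code{table}.
#' @export
bcrEnrichment <- function(moduleGenes, annotation, universe) {
  if (!length(universe)) stop("empty gene universe")
  ann <- annotation[match(universe, annotation$gene), ]
  coding <- universe[ann$coding]
  disease <- universe[ann$coding & ann$diseaseAssociated]
  inMod <- intersect(moduleGenes, coding)
  tab <- matrix(c(length(intersect(inMod, disease)),
                  length(setdiff(inMod, disease)),
                  length(setdiff(disease, inMod)),
                  length(setdiff(coding, union(inMod, disease)))),
                nrow = 2,
                dimnames = list(c("disease", "other"),
                                c("inModule", "outModule")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  list(p = p, table = tab)
}

#' Disease-relation scores for all modules of a stage
#'
#' \eqn{BCR_j = rescale(-\log_{10} p_j)} across the stage's modules,
#' where \eqn{p_j} is the Fisher enrichment p-value of module j.
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @param annotation Annotation data.frame.
#' @param universe Gene universe (all genes surviving preprocessing).
#' @return List with \code{score} (named, in [0, 1]) and \code{p}
#'   (named raw p-values).
#' @export
bcrScore <- function(partition, annotation, universe) {
  mods <- names(moduleSizes(partition))
  p <- vapply(mods, function(m)
    bcrEnrichment(moduleGenes(partition, m), annotation, universe)$p, 0)
  list(score = setNames(rescale01(-log10(p)), mods), p = p)
}

#' Cancer-reported non-coding fraction of a module
#'
#' Fraction of the module's non-coding genes that carry the
#' cancer-reported flag; 0 when the module contains no non-coding gene.
#'
#' @param moduleGenes Genes of the module.
#' @param annotation Annotation data.frame.
#' @return Numeric in [0, 1].
#' @export
bcrncrScore <- function(moduleGenes, annotation) {
  ann <- annotation[match(moduleGenes, annotation$gene), ]
  nc <- sum(!ann$coding, na.rm = TRUE)
  if (nc == 0) return(0)
  sum(!ann$coding & ann$ncCancerReported, na.rm = TRUE) / nc
}

#' Composite stage-specific disease score
#'
#' Sum of the stage-specificity (in [0, 2]), disease-relation (in [0, 1])
#' and non-coding relation (in [0, 1]) components; bounded in [0, 4].
#'
#' @param ss,bcr,bcrncr Score components.
#' @return Numeric in [0, 4].
#' @export
bcssScore <- function(ss, bcr, bcrncr) {
  if (any(ss < 0 | ss > 2)) stop("ss component out of [0, 2]")
  if (any(bcr < 0 | bcr > 1)) stop("bcr component out of [0, 1]")
  if (any(bcrncr < 0 | bcrncr > 1)) stop("bcrncr component out of [0, 1]")
  ss + bcr + bcrncr
}

#' Score every module of one stage
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @param preservation A \linkS4class{PreservationResult} for the stage.
#' @param annotation Annotation data.frame.
#' @param universe Gene universe.
#' @return data.frame(module, size, ss, bcr, bcrncr, bcss, fisherP)
#'   ordered by decreasing bcss.
#' @export
scoreModules <- function(partition, preservation, annotation, universe) {
  ss <- ssScore(preservation)
  mods <- names(ss)
  bcr <- bcrScore(partition, annotation, universe)
  ncr <- vapply(mods, function(m)
    bcrncrScore(moduleGenes(partition, m), annotation), 0)
  out <- data.frame(module = mods,
                    size = as.integer(moduleSizes(partition)[mods]),
                    ss = ss, bcr = bcr$score[mods], bcrncr = ncr,
                    bcss = bcssScore(ss, bcr$score[mods], ncr),
                    fisherP = bcr$p[mods], row.names = NULL)
  out[order(-out$bcss, -out$size, out$module), ]
}

#' Select the stage-specific disease-related module
#'
#' The module with maximal composite score; ties are broken by module
#' size (larger wins), then by label order.
#'
#' @param scores data.frame from [scoreModules()].
#' @return Module label.
#' @export
selectTopModule <- function(scores) {
  if (!nrow(scores)) stop("no module to select from")
  ord <- order(-scores$bcss, -scores$size, scores$module)
  scores$module[ord[1]]
}
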