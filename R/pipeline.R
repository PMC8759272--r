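## End-to-end orchestration: simulate (or load) -> preprocess -> per-stage
## differential networks, modules, preservation and composite scoring ->
## survival modelling on the selected genes -> re-wiring across
## consecutive conditions. One master seed drives every stochastic step
## through a fixed offset scheme (simulation: seed, annotations: seed+1,
## survival: seed+2, preservation for stage k: seed+10+k, SVM: seed+20).

#' Pipeline configuration
#'
#' Either a \linkS4class{SimulationConfig} (synthetic run) or paths to
#' counts/design/annotation TSV files (real-data run) plus the tuning
#' parameters of every stage.
#'
#' @param simulation A \linkS4class{SimulationConfig}, or NULL.
#' @param countsFile,designFile,annotationFile TSV paths, or NULL.
#' @param beta,useTom Differential-dissimilarity parameters.
#' @param mergeHeight,minModuleSize,cutHeight Module-detection parameters.
#' @param nPerm Preservation permutations per stage.
#' @param cpmThreshold,connectivityThreshold Preprocessing cutoffs.
#' @param rewireCutoff Edge-presence cutoff for the re-wiring networks.
#' @param vifThreshold VIF pruning threshold.
#' @param seed Master seed.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(simulation = NULL, countsFile = NULL,
                           designFile = NULL, annotationFile = NULL,
                           beta = 6L, useTom = TRUE, mergeHeight = 0.2,
                           minModuleSize = 10L, cutHeight = 0.99,
                           nPerm = 50L, cpmThreshold = 0.5,
                           connectivityThreshold = 0.1,
                           rewireCutoff = 0.7, vifThreshold = 10,
                           seed = 1L) {
  cfg <- list(simulation = simulation, countsFile = countsFile,
              designFile = designFile, annotationFile = annotationFile,
              beta = as.integer(beta), useTom = useTom,
              mergeHeight = mergeHeight,
              minModuleSize = as.integer(minModuleSize),
              cutHeight = cutHeight, nPerm = as.integer(nPerm),
              cpmThreshold = cpmThreshold,
              connectivityThreshold = connectivityThreshold,
              rewireCutoff = rewireCutoff, vifThreshold = vifThreshold,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  validatePipelineConfig(cfg)
  cfg
}

validatePipelineConfig <- function(cfg) {
  hasSim <- !is.null(cfg$simulation)
  hasFiles <- !is.null(cfg$countsFile)
  if (!hasSim && !hasFiles)
    stop("config needs either a simulation block or input file paths")
  if (hasSim && hasFiles)
    stop("config cannot carry both a simulation block and input files")
  if (hasSim) methods::validObject(cfg$simulation)
  if (hasFiles) {
    for (f in c(cfg$countsFile, cfg$designFile, cfg$annotationFile))
      if (!is.null(f) && !file.exists(f))
        stop("input file not found: ", f)
  }
  if (cfg$nPerm < 1) stop("nPerm must be at least 1")
  invisible(cfg)
}

#' Read a count matrix, design and annotation from TSV files
#'
#' \code{countsFile}: genes in rows (first column = gene id), samples in
#' columns. \code{designFile}: columns sample, condition and optionally
#' time, event. \code{annotationFile}: columns gene, coding,
#' diseaseAssociated, ncCancerReported.
#'
#' @param countsFile,designFile,annotationFile TSV paths
#'   (\code{annotationFile} may be NULL).
#' @return List: counts (matrix), design (data.frame), annotation
#'   (data.frame or NULL).
#' @export
readStageData <- function(countsFile, designFile, annotationFile = NULL) {
  for (f in c(countsFile, designFile, annotationFile))
    if (!file.exists(f)) stop("input file not found: ", f)
  ctab <- utils::read.delim(countsFile, check.names = FALSE)
  counts <- as.matrix(ctab[, -1, drop = FALSE])
  rownames(counts) <- ctab[[1]]
  design <- utils::read.delim(designFile)
  annotation <- if (!is.null(annotationFile))
    utils::read.delim(annotationFile) else NULL
  list(counts = counts, design = design, annotation = annotation)
}

#' Run the full stage re-wiring pipeline
#'
#' Executes preprocessing, per-stage differential co-expression module
#' detection, preservation scoring, composite module selection, survival
#' modelling on the selected genes and re-wiring classification across
#' consecutive conditions. With a fixed configuration (including the
#' seed) the returned report is bit-identical across runs.
#'
#' @param config A \code{PipelineConfig} from [pipelineConfig()].
#' @param dryRun Validate the configuration and return without
#'   computing.
#' @return A \code{ReportBundle}: list with elements \code{filterReport},
#'   \code{stages} (per-stage module score tables + selection),
#'   \code{selectedGenes}, \code{prognostic}, \code{riskModel},
#'   \code{strata}, \code{rewiring}, \code{svm} and \code{provenance}.
#' @export
runPipeline <- function(config, dryRun = FALSE) {
  validatePipelineConfig(config)
  if (dryRun) return(invisible(config))
  seed <- config$seed

  ## ---- inputs ----
  if (!is.null(config$simulation)) {
    sim <- simulateStageData(config$simulation)
    annotation <- simulateAnnotations(
      rownames(sim$counts), config$simulation@annotationFractions,
      seed = seed + 1L)
    counts <- sim$counts; design <- sim$design
    survSpec <- config$simulation@survival
  } else {
    inp <- readStageData(config$countsFile, config$designFile,
                         config$annotationFile)
    counts <- inp$counts; design <- inp$design
    annotation <- inp$annotation
    survSpec <- NULL
  }
  se <- StageExperiment(counts, design$condition, annotation = annotation)

  ## ---- preprocessing ----
  se <- preprocessCounts(se, config$cpmThreshold,
                         config$connectivityThreshold)
  expr <- SummarizedExperiment::assay(se, "logcpm")
  universe <- rownames(expr)
  cond <- stageConditions(se)

  ## ---- survival table ----
  tumour <- colnames(se)[cond != "normal"]
  surv <- if (!is.null(survSpec)) {
    ## hazards act on the cohort's expression itself, before any
    ## filtering: use log-CPM of the raw counts for the risk genes
    exprRaw <- log2(sweep(counts, 2, colSums(counts), "/") * 1e6 + 1)
    simulateSurvival(exprRaw[, tumour, drop = FALSE], survSpec,
                     seed = seed + 2L)
  } else if (all(c("time", "event") %in% colnames(design))) {
    data.frame(sample = design$sample, time = design$time,
               event = design$event)[design$sample %in% tumour, ]
  } else NULL

  ## ---- per-stage differential modules and scoring ----
  stages <- c("I", "II", "III", "IV")
  stageResults <- list()
  selectedGenes <- character(0)
  for (k in seq_along(stages)) {
    s <- stages[k]
    sStage <- colnames(se)[as.character(cond) == s]
    sRest <- setdiff(colnames(se), sStage)
    netStage <- correlationNetwork(expr, sStage, condition = s)
    netRest <- correlationNetwork(expr, sRest,
                                  condition = paste0("rest-", s))
    diff <- differentialDissimilarity(netStage, netRest,
                                      beta = config$beta,
                                      useTom = config$useTom)
    partition <- detectModules(diff, config$mergeHeight,
                               config$minModuleSize, config$cutHeight)
    if (!length(moduleSizes(partition))) {
      stageResults[[s]] <- list(scores = NULL, selected = NA_character_,
                                partition = moduleLabels(partition))
      next
    }
    pres <- preservationStats(partition, refNet = netRest,
                              testNet = netStage, nPerm = config$nPerm,
                              seed = seed + 10L + k)
    scores <- scoreModules(partition, pres, annotation, universe)
    scores$class <- classifyPreservation(
      pres@stats$Zsummary[match(scores$module, pres@stats$module)])
    scores$permP <- nonrandomnessTest(pres)[scores$module]
    top <- selectTopModule(scores)
    stageResults[[s]] <- list(scores = scores, selected = top,
                              partition = moduleLabels(partition))
    selectedGenes <- union(selectedGenes, moduleGenes(partition, top))
  }

  ## ---- survival analyses on the selected genes ----
  prognostic <- riskModelSummary <- strata <- svm <- NULL
  if (!is.null(surv) && length(selectedGenes)) {
    exprT <- expr[, surv$sample, drop = FALSE]
    prognostic <- do.call(rbind, lapply(selectedGenes, function(g) {
      km <- kmLogrank(expr[g, surv$sample], surv)
      tr <- classifyTrends(expr[g, ],
                           data.frame(sample = colnames(se),
                                      condition = cond))
      data.frame(gene = g, logrankP = km$p, prognostic = km$prognostic,
                 trendClass = tr$class, kwP = tr$kwP,
                 outsetP = tr$outsetP)
    }))
    progGenes <- prognostic$gene[prognostic$prognostic]
    if (length(progGenes) >= 2) {
      kept <- vifSelect(t(exprT[progGenes, , drop = FALSE]),
                        config$vifThreshold)
      model <- fitCoxRisk(kept, exprT, surv)
      riskModelSummary <- list(covariates = model@covariates,
                               coefficients = model@coefficients,
                               hazardRatios = model@hazardRatios,
                               lrTestP = model@lrTestP,
                               cIndex = model@cIndex,
                               strataThresholds = model@strataThresholds)
      strata <- table(stratifyRisk(model, exprT))
    }
    outset <- prognostic$gene[prognostic$trendClass == "outset-cancer"]
    normI <- colnames(se)[as.character(cond) %in% c("normal", "I")]
    if (length(outset) >= 1 &&
        all(table(cond[colnames(se) %in% normI]) [c("normal", "I")] >= 5)) {
      svm <- svmValidate(expr[outset, normI, drop = FALSE],
                         factor(as.character(cond)[colnames(se) %in% normI],
                                levels = c("normal", "I")),
                         seed = seed + 20L)
      svm$fold <- NULL
    }
  }

  ## ---- re-wiring across consecutive conditions ----
  rewiring <- NULL
  rewGenes <- if (!is.null(prognostic) && sum(prognostic$prognostic) >= 2)
    prognostic$gene[prognostic$prognostic] else selectedGenes
  if (length(rewGenes) >= 2) {
    nets <- lapply(CONDITION_LEVELS, function(cc)
      suppressWarnings(
        conditionNetwork(expr, colnames(se)[as.character(cond) == cc],
                         rewGenes, condition = cc,
                         cutoff = config$rewireCutoff)))
    names(nets) <- CONDITION_LEVELS
    rewiring <- lapply(seq_len(4), function(i)
      classifyRewiring(nets[[i]], nets[[i + 1]]))
    names(rewiring) <- paste(CONDITION_LEVELS[1:4], CONDITION_LEVELS[2:5],
                             sep = "->")
  }
  rewiringSummary <- if (!is.null(rewiring)) do.call(rbind, lapply(
    names(rewiring), function(tr) {
      e <- rewiring[[tr]]@edges
      data.frame(transition = tr, gain = sum(e$class == "gain"),
                 loss = sum(e$class == "loss"),
                 reversed = sum(e$class == "reversed"),
                 hubs = paste(rewiring[[tr]]@hubs, collapse = ","))
    })) else NULL

  report <- list(
    filterReport = S4Vectors::metadata(se)$filterReport,
    stages = stageResults,
    selectedGenes = sort(selectedGenes),
    prognostic = prognostic,
    riskModel = riskModelSummary,
    strata = strata,
    rewiring = rewiringSummary,
    rewiringEdges = lapply(rewiring, function(r) r@edges),
    svm = svm,
    provenance = list(seed = seed, beta = config$beta,
                      mergeHeight = config$mergeHeight,
                      nPerm = config$nPerm,
                      rewireCutoff = config$rewireCutoff))
  class(report) <- "ReportBundle"
  report
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle (seed", x$provenance$seed, ")\n")
  cat("genes after preprocessing:",
      x$filterReport[["connectivity"]], "\n")
  for (s in names(x$stages))
    cat("stage ", s, ": selected ", x$stages[[s]]$selected, "\n", sep = "")
  if (!is.null(x$prognostic))
    cat("prognostic genes:", sum(x$prognostic$prognostic), "of",
        nrow(x$prognostic), "\n")
  if (!is.null(x$riskModel))
    cat("risk model: ", length(x$riskModel$covariates),
        " covariates, c-index = ", round(x$riskModel$cIndex, 3), "\n",
        sep = "")
  if (!is.null(x$rewiring)) print(x$rewiring[, 1:4])
  invisible(x)
}
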