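## Seeded multi-stage RNA-seq simulator with planted co-expression
## re-wiring. The latent model is log-normal: each gene's log-expression is
## meanLog + noiseSd * z, with z standard normal and, inside a planted
## module, equicorrelated at the module's per-condition intra-correlation
## via a one-factor construction. Counts are Poisson draws around
## library-size-scaled relative expression, so re-wiring lives purely in
## the correlation structure, never in the mean.

#' Planted co-expression module
#'
#' Describes one block of genes whose latent log-expression is
#' equicorrelated within each condition at a condition-specific level.
#' Changing the correlation across conditions plants re-wiring; the mean
#' is shared by all conditions so re-wired modules are not differentially
#' expressed.
#'
#' @slot geneIds Genes belonging to the module.
#' @slot intraCorrelation Named numeric, one entry per condition
#'   (normal, I, II, III, IV), each in [0, 1).
#' @slot meanLogExpression Latent mean log-expression of the module.
#' @export
setClass("PlantedModule",
  representation(geneIds = "character", intraCorrelation = "numeric",
                 meanLogExpression = "numeric"))

setValidity("PlantedModule", function(object) {
  rho <- object@intraCorrelation
  if (!setequal(names(rho), CONDITION_LEVELS))
    return("intraCorrelation needs one entry per condition")
  if (any(rho < 0))
    return(paste("negative intra-correlations are not supported: an",
                 "equicorrelated block of size k is only positive",
                 "semi-definite for rho >= -1/(k-1)"))
  if (any(rho > 1)) return("intra-correlation must lie in [0, 1]")
  if (anyDuplicated(object@geneIds)) return("duplicate gene ids in module")
  TRUE
})

#' @rdname PlantedModule-class
#' @param geneIds Character vector of gene identifiers.
#' @param intraCorrelation Named numeric of per-condition correlations;
#'   conditions left out default to 0.
#' @param meanLogExpression Latent mean log-expression (default 5).
#' @export
plantedModule <- function(geneIds, intraCorrelation,
                          meanLogExpression = 5) {
  rho <- setNames(rep(0, length(CONDITION_LEVELS)), CONDITION_LEVELS)
  rho[names(intraCorrelation)] <- intraCorrelation
  methods::new("PlantedModule", geneIds = as.character(geneIds),
               intraCorrelation = rho,
               meanLogExpression = meanLogExpression)
}

#' Survival effect specification
#'
#' Event times follow an exponential model whose log-hazard is
#' \code{logHazardPerUnit} times the standardized mean expression of the
#' risk genes; censoring is independent exponential tuned to the target
#' censored fraction.
#'
#' @slot riskGenes Genes driving the hazard.
#' @slot logHazardPerUnit Log hazard ratio per SD of the risk score.
#' @slot baselineScale Baseline mean event time (days).
#' @slot censoringRate Target censored fraction in [0, 1).
#' @export
setClass("SurvivalEffectSpec",
  representation(riskGenes = "character", logHazardPerUnit = "numeric",
                 baselineScale = "numeric", censoringRate = "numeric"))

setValidity("SurvivalEffectSpec", function(object) {
  if (object@baselineScale <= 0) return("baselineScale must be positive")
  cr <- object@censoringRate
  if (cr < 0 || cr >= 1) return("censoringRate must lie in [0, 1)")
  if (!length(object@riskGenes) && object@logHazardPerUnit != 0)
    return("empty riskGenes with a nonzero hazard effect")
  TRUE
})

#' @rdname SurvivalEffectSpec-class
#' @param riskGenes,logHazardPerUnit,baselineScale,censoringRate See slots.
#' @export
survivalEffectSpec <- function(riskGenes, logHazardPerUnit = log(2),
                               baselineScale = 1000, censoringRate = 0.2) {
  methods::new("SurvivalEffectSpec", riskGenes = as.character(riskGenes),
               logHazardPerUnit = logHazardPerUnit,
               baselineScale = baselineScale, censoringRate = censoringRate)
}

#' Simulation configuration
#'
#' Full description of a synthetic multi-stage cohort: gene universe,
#' per-condition sample sizes, planted modules, library-size range, latent
#' noise, survival effect and annotation fractions, all driven by one seed.
#'
#' @slot nGenes Total number of genes.
#' @slot nSamplesPerCondition Named integer, samples per condition.
#' @slot modules List of \linkS4class{PlantedModule}.
#' @slot librarySizeRange Range the per-sample sequencing depths are drawn
#'   from (uniform).
#' @slot noiseSd SD of the latent log-expression around its mean.
#' @slot baselineLogExpression Latent mean for background genes.
#' @slot survival A \linkS4class{SurvivalEffectSpec}.
#' @slot annotationFractions Named numeric: \code{noncoding},
#'   \code{disease}, \code{ncReported}.
#' @slot seed Integer master seed; all sub-generators derive from it.
#' @export
setClass("SimulationConfig",
  representation(nGenes = "integer", nSamplesPerCondition = "integer",
                 modules = "list", librarySizeRange = "numeric",
                 noiseSd = "numeric", baselineLogExpression = "numeric",
                 survival = "SurvivalEffectSpec",
                 annotationFractions = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  ns <- object@nSamplesPerCondition
  if (!setequal(names(ns), CONDITION_LEVELS))
    return("nSamplesPerCondition needs one entry per condition")
  if (any(ns < 3L)) return("every condition needs at least 3 samples")
  allMod <- unlist(lapply(object@modules, function(m) m@geneIds))
  if (anyDuplicated(allMod))
    return("planted module gene sets must be disjoint")
  if (object@nGenes < length(allMod))
    return("nGenes must be at least the sum of planted module sizes")
  fr <- object@annotationFractions
  if (!all(c("noncoding", "disease", "ncReported") %in% names(fr)))
    return("annotationFractions needs noncoding, disease, ncReported")
  if (any(fr < 0) || any(fr > 1)) return("fractions must lie in [0, 1]")
  if (fr["ncReported"] > fr["noncoding"])
    return("ncReported fraction cannot exceed the noncoding fraction")
  lr <- object@librarySizeRange
  if (length(lr) != 2L || any(lr <= 0) || lr[1] > lr[2])
    return("librarySizeRange must be two positive increasing numbers")
  if (object@noiseSd < 0) return("noiseSd must be nonnegative")
  TRUE
})

#' @rdname SimulationConfig-class
#'
#' @details The default configuration emulates the study cohort this
#' package was designed around: an ER-positive breast-cancer series with
#' 113 normal, 40 stage-I, 92 stage-II, 55 stage-III and 15 stage-IV
#' samples, a desk-scale universe of 300 genes, and four planted modules
#' of 50 genes each. Module \eqn{m} is tightly co-expressed
#' (\eqn{\rho = 0.85}) in every condition except its target stage, where
#' the co-expression collapses to 0 — i.e. each module is re-wired in, and
#' therefore specific to, exactly one stage. The first ten genes of the
#' stage-I module additionally drive survival with a hazard ratio of 2 per
#' SD of their mean expression and 20\% censoring.
#'
#' @param nGenes,nSamplesPerCondition,modules,librarySizeRange,noiseSd See
#'   slots; any argument left \code{NULL} takes the default cohort value.
#' @param baselineLogExpression,survival,annotationFractions,seed See slots.
#' @examples
#' cfg <- simulationConfig(seed = 7L)
#' sim <- simulateStageData(cfg)
#' dim(sim$counts)
#' @export
simulationConfig <- function(nGenes = 300L,
                             nSamplesPerCondition = NULL,
                             modules = NULL,
                             librarySizeRange = c(8e5, 1.2e6),
                             noiseSd = 0.6,
                             baselineLogExpression = 5,
                             survival = NULL,
                             annotationFractions = c(noncoding = 0.25,
                                                     disease = 0.15,
                                                     ncReported = 0.10),
                             seed = 1L) {
  if (is.null(nSamplesPerCondition))
    nSamplesPerCondition <- c(normal = 113L, I = 40L, II = 92L,
                              III = 55L, IV = 15L)
  geneIds <- sprintf("gene_%04d", seq_len(nGenes))
  if (is.null(modules)) {
    stages <- c("I", "II", "III", "IV")
    modules <- lapply(seq_along(stages), function(m) {
      rho <- setNames(rep(0.85, 5), CONDITION_LEVELS)
      rho[stages[m]] <- 0
      plantedModule(geneIds[((m - 1) * 50 + 1):(m * 50)], rho)
    })
  }
  if (is.null(survival))
    survival <- survivalEffectSpec(riskGenes = modules[[1]]@geneIds[1:10])
  methods::new("SimulationConfig", nGenes = as.integer(nGenes),
               nSamplesPerCondition =
                 setNames(as.integer(nSamplesPerCondition),
                          names(nSamplesPerCondition)),
               modules = modules, librarySizeRange = librarySizeRange,
               noiseSd = noiseSd,
               baselineLogExpression = baselineLogExpression,
               survival = survival,
               annotationFractions = annotationFractions,
               seed = as.integer(seed))
}

#' Simulate a multi-stage count dataset
#'
#' Draws a gene x sample count matrix with planted per-condition
#' co-expression blocks. For every sample, a sequencing depth is drawn
#' uniformly from the configured range; each gene's expected count is the
#' depth times its relative latent expression, and the observed count is a
#' Poisson draw around it. Within a planted module, the latent standard
#' normals share a one-factor structure that induces the configured
#' intra-correlation for that sample's condition.
#'
#' Identical configuration (including seed) gives bit-identical output.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return List with \code{counts} (integer matrix), \code{design}
#'   (data.frame: sample, condition, librarySize) and \code{truth}
#'   (the list of planted modules).
#' @export
simulateStageData <- function(config) {
  methods::validObject(config)
  geneIds <- sprintf("gene_%04d", seq_len(config@nGenes))
  ns <- config@nSamplesPerCondition[CONDITION_LEVELS]
  nTot <- sum(ns)
  cond <- rep(CONDITION_LEVELS, ns)
  sampleIds <- sprintf("sample_%03d", seq_len(nTot))

  meanLog <- rep(config@baselineLogExpression, config@nGenes)
  names(meanLog) <- geneIds
  for (m in config@modules) meanLog[m@geneIds] <- m@meanLogExpression

  withSeed(config@seed, {
    libSizes <- runif(nTot, config@librarySizeRange[1],
                      config@librarySizeRange[2])
    counts <- matrix(0L, config@nGenes, nTot,
                     dimnames = list(geneIds, sampleIds))
    for (cc in CONDITION_LEVELS) {
      idx <- which(cond == cc)
      n <- length(idx)
      z <- matrix(rnorm(config@nGenes * n), config@nGenes, n,
                  dimnames = list(geneIds, NULL))
      for (m in config@modules) {
        rho <- m@intraCorrelation[cc]
        if (rho > 0) {
          f <- rnorm(n)  # shared module factor per sample
          z[m@geneIds, ] <- sqrt(rho) * rep(f, each = length(m@geneIds)) +
            sqrt(1 - rho) * z[m@geneIds, ]
        }
      }
      x <- meanLog + config@noiseSd * z
      w <- exp(x)
      lambda <- sweep(w, 2, colSums(w), "/") *
        rep(libSizes[idx], each = config@nGenes)
      counts[, idx] <- rpois(length(lambda), lambda)
    }
    design <- data.frame(sample = sampleIds,
                         condition = factor(cond,
                                            levels = CONDITION_LEVELS),
                         librarySize = libSizes)
    list(counts = counts, design = design, truth = config@modules)
  })
}

#' Simulate gene annotations
#'
#' Assigns coding/non-coding status, a disease-association flag (among
#' coding genes, emulating a disease-gene list) and a
#' cancer-reported-non-coding flag (among non-coding genes) by seeded
#' sampling. Flag counts are deterministic: \code{round(fraction * n)}.
#'
#' @param geneIds Gene identifiers.
#' @param fractions Named numeric: \code{noncoding}, \code{disease},
#'   \code{ncReported}, each in [0, 1] with
#'   \code{ncReported <= noncoding}.
#' @param seed Integer seed.
#' @return data.frame(gene, coding, diseaseAssociated, ncCancerReported).
#' @export
simulateAnnotations <- function(geneIds, fractions, seed) {
  if (any(fractions < 0) || any(fractions > 1))
    stop("annotation fractions must lie in [0, 1]")
  if (fractions["ncReported"] > fractions["noncoding"])
    stop("ncReported fraction cannot exceed the noncoding fraction")
  n <- length(geneIds)
  nNC <- round(fractions[["noncoding"]] * n)
  nDis <- round(fractions[["disease"]] * n)
  nRep <- round(fractions[["ncReported"]] * n)
  withSeed(seed, {
    nc <- sample(geneIds, nNC)
    codingGenes <- setdiff(geneIds, nc)
    if (nDis > length(codingGenes))
      stop("disease fraction exceeds the available coding genes")
    dis <- sample(codingGenes, nDis)
    rep_ <- if (nRep > 0) sample(nc, nRep) else character(0)
    data.frame(gene = geneIds,
               coding = !(geneIds %in% nc),
               diseaseAssociated = geneIds %in% dis,
               ncCancerReported = geneIds %in% rep_,
               row.names = NULL)
  })
}

#' Simulate overall-survival follow-up
#'
#' Event times are exponential with per-patient rate
#' \eqn{\exp(\beta s_i) / \mathrm{baselineScale}}, where \eqn{s_i} is the
#' standardized mean expression of the risk genes. Censoring times are
#' independent exponentials whose rate is tuned so that roughly the
#' configured fraction of patients is censored; a censoring rate of zero
#' yields no censoring at all.
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param spec A \linkS4class{SurvivalEffectSpec}.
#' @param seed Integer seed.
#' @return data.frame(sample, time, event) with strictly positive times.
#' @export
simulateSurvival <- function(expr, spec, seed) {
  methods::validObject(spec)
  missing <- setdiff(spec@riskGenes, rownames(expr))
  if (length(missing))
    stop("risk genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  n <- ncol(expr)
  score <- if (length(spec@riskGenes)) {
    as.numeric(scale(colMeans(expr[spec@riskGenes, , drop = FALSE])))
  } else rep(0, n)
  if (any(!is.finite(score))) score[!is.finite(score)] <- 0
  withSeed(seed, {
    rate <- exp(spec@logHazardPerUnit * score) / spec@baselineScale
    tEvent <- rexp(n, rate)
    if (spec@censoringRate > 0) {
      cr <- spec@censoringRate
      rateC <- (cr / (1 - cr)) / spec@baselineScale
      tCens <- rexp(n, rateC)
      time <- pmin(tEvent, tCens)
      event <- as.integer(tEvent <= tCens)
    } else {
      time <- tEvent
      event <- rep(1L, n)
    }
    data.frame(sample = colnames(expr), time = time, event = event,
               row.names = NULL)
  })
}
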