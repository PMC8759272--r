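## Permutation-based module preservation between a reference and a test
## network. A reduced set of four statistics is used — two density
## statistics (mean within-module correlation, mean within-module
## absolute adjacency, both in the test network) and two connectivity
## statistics (correlation of intramodular connectivities between the two
## networks, correlation of the within-module correlation vectors). Each
## is Z-scored against permutations of the module labels among clustered
## genes; Zsummary is the mean of the density and connectivity medians.

## The four raw statistics for one gene set.
modulePreservationStats <- function(genes, refA, testA) {
  rT <- testA[genes, genes, drop = FALSE]
  rR <- refA[genes, genes, drop = FALSE]
  ut <- upper.tri(rT)
  kR <- rowSums(abs(rR)) - 1
  kT <- rowSums(abs(rT)) - 1
  corKIM <- suppressWarnings(cor(kR, kT))
  corCor <- suppressWarnings(cor(rR[ut], rT[ut]))
  c(meanCor = mean(rT[ut]),
    meanAdj = mean(abs(rT[ut])),
    corKIM = if (is.finite(corKIM)) corKIM else 0,
    corCor = if (is.finite(corCor)) corCor else 0)
}

#' Permutation preservation statistics per module
#'
#' Computes, for every module of at least 3 genes, density and
#' connectivity preservation statistics of the module in \code{testNet}
#' relative to \code{refNet}, Z-scored against \code{nPerm} size-matched
#' random gene sets drawn from the whole network (module sizes preserved,
#' draws disjoint within a permutation). \code{Zsummary} is the mean of
#' the median density Z and
#' the median connectivity Z; \code{Medianrank} is the median across
#' statistics of the module's observed-statistic rank (rank 1 = most
#' preserved). Low \code{Zsummary} and high \code{Medianrank} mark a
#' condition-specific (non-preserved) module.
#'
#' @param partition A \linkS4class{ModulePartition}.
#' @param refNet,testNet \linkS4class{CoexpressionNetwork}s covering the
#'   partition's genes.
#' @param nPerm Number of permutations (>= 1; >= 20 for reported results).
#' @param seed Integer seed for the permutation draws.
#' @return A \linkS4class{PreservationResult}.
#' @export
preservationStats <- function(partition, refNet, testNet, nPerm = 100L,
                              seed = 1L) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be at least 1")
  lab <- partition@labels
  clustered <- names(lab)[lab != "unassigned"]
  missing <- setdiff(clustered, rownames(refNet@adjacency))
  missing <- union(missing, setdiff(clustered, rownames(testNet@adjacency)))
  if (length(missing))
    stop("partition genes absent from a network: ",
         paste(missing, collapse = ", "))
  mods <- names(moduleSizes(partition))
  small <- mods[moduleSizes(partition) < 3L]
  if (length(small)) {
    warning("skipping modules with fewer than 3 genes: ",
            paste(small, collapse = ", "))
    mods <- setdiff(mods, small)
  }
  if (!length(mods)) stop("no module with at least 3 genes")
  refA <- refNet@adjacency; testA <- testNet@adjacency

  obs <- t(vapply(mods, function(m)
    modulePreservationStats(moduleGenes(partition, m), refA, testA),
    numeric(4)))

  ## null modules: size-matched gene sets drawn from the whole network,
  ## module sizes preserved and draws disjoint within one permutation
  pool0 <- sort(intersect(rownames(refA), rownames(testA)))
  sizes <- moduleSizes(partition)[mods]
  perm <- withSeed(seed, {
    lapply(seq_len(nPerm), function(p) {
      pool <- sample(pool0)
      off <- 0L
      t(vapply(seq_along(mods), function(j) {
        g <- pool[(off + 1L):(off + sizes[j])]
        off <<- off + sizes[j]
        modulePreservationStats(g, refA, testA)
      }, numeric(4)))
    })
  })
  permArr <- array(unlist(perm), dim = c(length(mods), 4, nPerm),
                   dimnames = list(mods, colnames(obs), NULL))
  permMean <- apply(permArr, c(1, 2), mean)
  permSd <- apply(permArr, c(1, 2), sd)

  ## a statistic whose permutation distribution is a point mass carries
  ## no evidence (e.g. connectivity correlations when refNet == testNet);
  ## it is excluded from the summary rather than counted as zero
  zOf <- function(stat) {
    z <- (stat - permMean) / permSd
    z[permSd < 1e-12] <- NA_real_
    z[!is.finite(z)] <- NA_real_
    z
  }
  meanOrNA <- function(m) {
    out <- rowMeans(m, na.rm = TRUE)
    out[!is.finite(out)] <- NA_real_
    out
  }
  zObs <- zOf(obs)
  zDensity <- meanOrNA(zObs[, c("meanCor", "meanAdj"), drop = FALSE])
  zConnectivity <- meanOrNA(zObs[, c("corKIM", "corCor"), drop = FALSE])
  zSummary <- meanOrNA(cbind(zDensity, zConnectivity))
  zSummary[is.na(zSummary)] <- 0

  ## rank 1 = most preserved = highest observed statistic
  ranks <- apply(-obs, 2, rank, ties.method = "average")
  if (length(mods) == 1L) ranks <- matrix(1, 1, 4, dimnames = dimnames(obs))
  medianrank <- apply(ranks, 1, median)

  permZ <- vapply(seq_len(nPerm), function(p) {
    z <- zOf(permArr[, , p, drop = TRUE])
    if (length(mods) == 1L) z <- matrix(z, 1, 4, dimnames = dimnames(obs))
    zs <- meanOrNA(cbind(
      meanOrNA(z[, c("meanCor", "meanAdj"), drop = FALSE]),
      meanOrNA(z[, c("corKIM", "corCor"), drop = FALSE])))
    zs[is.na(zs)] <- 0
    zs
  }, numeric(length(mods)))
  permZ <- matrix(t(permZ), nrow = nPerm, ncol = length(mods),
                  dimnames = list(NULL, mods))

  stats <- data.frame(module = mods, meanCor = obs[, "meanCor"],
                      meanAdj = obs[, "meanAdj"], corKIM = obs[, "corKIM"],
                      corCor = obs[, "corCor"], Zdensity = zDensity,
                      Zconnectivity = zConnectivity, Zsummary = zSummary,
                      Medianrank = medianrank, row.names = NULL)
  methods::new("PreservationResult", stats = stats, permZsummary = permZ,
               nPerm = nPerm, seed = as.integer(seed))
}

#' Classify a Zsummary value
#'
#' Modules with \code{Zsummary < 2} are not preserved in the test network
#' and hence condition-specific; values above 10 indicate a preserved
#' (non-specific) module; the closed interval [2, 10] is moderate.
#'
#' @param z Numeric vector of Zsummary values.
#' @return Character vector: \code{"stage-specific"},
#'   \code{"moderately stage-specific"} or \code{"not stage-specific"}.
#' @export
classifyPreservation <- function(z) {
  ifelse(z < 2, "stage-specific",
         ifelse(z <= 10, "moderately stage-specific",
                "not stage-specific"))
}

#' Permutation non-randomness test of stage specificity
#'
#' Empirical p-value per module that a random, size-matched gene set
#' would look at least as stage-specific (i.e. have a Zsummary at least
#' as low) as the observed module, using the permutation draws stored in
#' the result: \eqn{p = (1 + \#\{Z^{perm} \le Z^{obs}\}) / (nPerm + 1)}.
#'
#' @param result A \linkS4class{PreservationResult} (with
#'   \code{nPerm >= 20} for reportable p-values).
#' @return Named numeric vector of p-values in (0, 1].
#' @export
nonrandomnessTest <- function(result) {
  if (result@nPerm < 20L)
    warning("fewer than 20 permutations; p-values are coarse")
  obs <- setNames(result@stats$Zsummary, result@stats$module)
  vapply(names(obs), function(m) {
    (1 + sum(result@permZsummary[, m] <= obs[m])) / (result@nPerm + 1)
  }, 0)
}
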