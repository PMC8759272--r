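## Shared fixtures and small independent oracles, all built in code.

## Adjusted Rand index between two label vectors (independent of the
## package's clustering code).
ariIndex <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  (sumij - expected) / ((ai + bj) / 2 - expected)
}

## Expression matrix with one equicorrelated block and independent noise
## genes; used for network/preservation fixtures.
blockExpr <- function(nBlock = 30, nNoise = 70, n = 60, rho = 0.9,
                      seed = 1, gradient = FALSE) {
  set.seed(seed)
  f <- rnorm(n)
  ## gradient = TRUE gives the block a hub structure (decreasing factor
  ## loadings) so intramodular connectivity carries gene-specific signal
  l <- if (gradient) sqrt(rho) * seq(1, 0.55, length.out = nBlock)
       else rep(sqrt(rho), nBlock)
  block <- l %o% f + sqrt(1 - l^2) * matrix(rnorm(nBlock * n), nBlock)
  x <- rbind(block, matrix(rnorm(nNoise * n), nNoise))
  rownames(x) <- sprintf("g%03d", seq_len(nBlock + nNoise))
  colnames(x) <- sprintf("s%03d", seq_len(n))
  x
}

## Two-group dataset with four planted modules of 50 genes re-wired
## between the groups (rho = rhoA in group A conditions, rhoB in B).
rewiredTwoGroupSim <- function(seed, nPerGroup = 60, rhoA = 0.85,
                               rhoB = 0) {
  mods <- lapply(1:4, function(m)
    plantedModule(sprintf("gene_%04d", ((m - 1) * 50 + 1):(m * 50)),
                  c(normal = rhoA, I = rhoB, II = 0, III = 0, IV = 0)))
  cfg <- simulationConfig(
    nGenes = 300,
    nSamplesPerCondition = c(normal = nPerGroup, I = nPerGroup,
                             II = 3, III = 3, IV = 3),
    modules = mods, seed = seed)
  sim <- simulateStageData(cfg)
  expr <- log2(sweep(sim$counts, 2, colSums(sim$counts), "/") * 1e6 + 1)
  groupA <- sim$design$sample[sim$design$condition == "normal"]
  groupB <- sim$design$sample[sim$design$condition == "I"]
  list(expr = expr, groupA = groupA, groupB = groupB,
       truth = vapply(sprintf("gene_%04d", 1:300), function(g) {
         hit <- which(vapply(mods, function(m) g %in% m@geneIds, TRUE))
         if (length(hit)) paste0("planted_", hit) else "noise"
       }, ""))
}

## One-sided (enrichment) hypergeometric tail probability by direct
## enumeration of all at-least-as-enriched tables; independent of
## stats::fisher.test / phyper.
enumFisherGreater <- function(x, m, n, k) {
  xs <- seq.int(x, min(m, k))
  xs <- xs[xs >= max(0, k - n)]
  sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
}

## Build an annotation table in which the named module genes are
## disease-enriched and carry reported non-coding genes.
enrichedAnnotation <- function(universe, moduleGenes, seed = 1,
                               ncInModule = 10, diseaseFracIn = 0.6,
                               diseaseFracOut = 0.1) {
  set.seed(seed)
  outside <- setdiff(universe, moduleGenes)
  ncIn <- sample(moduleGenes, min(ncInModule, length(moduleGenes)))
  ncOut <- sample(outside, round(0.2 * length(outside)))
  nc <- c(ncIn, ncOut)
  codingIn <- setdiff(moduleGenes, nc)
  codingOut <- setdiff(outside, nc)
  disease <- c(sample(codingIn, round(diseaseFracIn * length(codingIn))),
               sample(codingOut, round(diseaseFracOut * length(codingOut))))
  data.frame(gene = universe,
             coding = !(universe %in% nc),
             diseaseAssociated = universe %in% disease,
             ncCancerReported = universe %in% ncIn,
             row.names = NULL)
}
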