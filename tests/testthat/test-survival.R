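## Independent log-rank permutation oracle: permute the expression
## vector, re-split at the median, and recompute the statistic.
logrankPermOracle <- function(exprGene, surv, nDraws, seed) {
  obs <- kmLogrank(exprGene, surv)$statistic
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nDraws)) {
    xp <- setNames(sample(unname(exprGene)), names(exprGene))
    hits <- hits + (kmLogrank(xp, surv)$statistic >= obs - 1e-12)
  }
  (1 + hits) / (nDraws + 1)
}

test_that("log-rank on identical groups is null; median ties go Low", {
  surv <- data.frame(sample = sprintf("p%02d", 1:8),
                     time = rep(c(5, 10, 15, 20), 2),
                     event = rep(1L, 8))
  ## expression splits into two groups carrying identical survival data
  x <- setNames(c(1, 1, 1, 1, 9, 9, 9, 9), surv$sample)
  km <- kmLogrank(x, surv)
  expect_equal(km$statistic, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  ## a value equal to the median lands in the Low group
  x2 <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), surv$sample)
  km2 <- kmLogrank(x2, surv)
  expect_identical(as.character(km2$group[4]), "Low")  # 4 < median 4.5
  x3 <- setNames(c(1, 1, 4, 4, 4, 9, 9, 9), surv$sample)
  km3 <- kmLogrank(x3, surv)
  expect_true(all(as.character(km3$group[x3 == 4]) == "Low"))
  expect_error(kmLogrank(setNames(rep(1, 8), surv$sample), surv),
               "fewer than 2")
})

test_that("log-rank p agrees with a permutation oracle at n = 40", {
  ## complete separation: every group-A event precedes group B
  surv <- data.frame(sample = sprintf("p%02d", 1:40),
                     time = c(seq(10, 200, length.out = 20),
                              seq(500, 900, length.out = 20)),
                     event = 1L)
  x <- setNames(c(rep(10, 20), rep(1, 20)), surv$sample)
  p <- kmLogrank(x, surv)$p
  pPerm <- logrankPermOracle(x, surv, nDraws = 2000, seed = 1)
  se <- sqrt(pPerm * (1 - pPerm) / 2000)
  expect_lte(abs(p - pPerm), 3 * se + 1e-12)
  ## moderate separation
  set.seed(7)
  surv2 <- data.frame(sample = sprintf("q%02d", 1:40),
                      time = c(rexp(20, 1 / 100), rexp(20, 1 / 220)),
                      event = rbinom(40, 1, 0.9))
  x2 <- setNames(c(rep(5, 20), rep(1, 20)), surv2$sample)
  p2 <- kmLogrank(x2, surv2)$p
  pPerm2 <- logrankPermOracle(x2, surv2, nDraws = 2000, seed = 2)
  se2 <- sqrt(pPerm2 * (1 - pPerm2) / 2000)
  expect_lte(abs(p2 - pPerm2), 3 * se2)
})

test_that("log-rank is invariant to monotone transforms of expression", {
  set.seed(3)
  surv <- data.frame(sample = sprintf("p%02d", 1:30),
                     time = rexp(30, 1 / 100), event = 1L)
  x <- setNames(runif(30, 1, 5), surv$sample)
  p1 <- kmLogrank(x, surv)$p
  p2 <- kmLogrank(exp(x), surv)$p
  p3 <- kmLogrank(rank(x) * 10, surv)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

trendDesign <- function(nPer = 30) {
  data.frame(sample = sprintf("s%03d", seq_len(5 * nPer)),
             condition = rep(c("normal", "I", "II", "III", "IV"),
                             each = nPer))
}

test_that("stage trends are classified from the Kruskal-Wallis/Dunn chain", {
  nPer <- 30
  design <- trendDesign(nPer)
  set.seed(11)
  ## clearly descending stage medians 5,4,3,2
  xDesc <- setNames(c(rnorm(nPer, 3), rnorm(nPer, 5, 0.4),
                      rnorm(nPer, 4, 0.4), rnorm(nPer, 3, 0.4),
                      rnorm(nPer, 2, 0.4)), design$sample)
  tDesc <- classifyTrends(xDesc, design)
  expect_identical(tDesc$class, "descending")
  expect_lt(tDesc$kwP, 0.05)
  ## ascending
  xAsc <- setNames(c(rnorm(nPer, 3), rnorm(nPer, 2, 0.4),
                     rnorm(nPer, 3, 0.4), rnorm(nPer, 4, 0.4),
                     rnorm(nPer, 5, 0.4)), design$sample)
  expect_identical(classifyTrends(xAsc, design)$class, "ascending")
  ## outset-cancer: normal low, all stages flat high
  xOut <- setNames(c(rnorm(nPer, 2, 0.5), rnorm(4 * nPer, 6, 0.5)),
                   design$sample)
  tOut <- classifyTrends(xOut, design)
  expect_identical(tOut$class, "outset-cancer")
  expect_lt(tOut$outsetP, 0.05)
  expect_error(classifyTrends(xOut[1:60], design[1:60, ]), "at least 3")
})

test_that("null expression yields 'none' at close to the nominal rate", {
  design <- trendDesign(15)
  calls <- vapply(1:10, function(s) {
    set.seed(600 + s)
    x <- setNames(rnorm(nrow(design)), design$sample)
    classifyTrends(x, design)$class
  }, "")
  expect_gte(mean(calls == "none"), 0.8)
})

test_that("BH adjustment preserves the order of raw p-values", {
  set.seed(2)
  design <- trendDesign(12)
  x <- setNames(c(rnorm(12, 2), rnorm(12, 2), rnorm(12, 2.5),
                  rnorm(12, 3), rnorm(12, 4)), design$sample)
  ph <- classifyTrends(x, design)$posthoc
  expect_identical(order(ph$p), order(ph$pAdj, ph$p))
  expect_true(all(ph$pAdj >= ph$p))
})

test_that("VIF pruning drops collinear covariates and keeps the rest", {
  set.seed(5)
  n <- 100
  ## mutually orthogonal covariates: all VIF 1, all kept
  X <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  colnames(X) <- paste0("v", 1:4)
  expect_equal(unname(vifValues(X)), rep(1, 4), tolerance = 1e-5)
  expect_identical(vifSelect(X), colnames(X))
  ## exact duplicate: one of the pair is dropped
  Xdup <- cbind(X, v5 = X[, "v1"])
  kept <- vifSelect(Xdup)
  expect_equal(length(kept), 4)
  expect_true(xor("v1" %in% kept, "v5" %in% kept))
  ## planted near-dependence: survivors all below threshold
  Xdep <- cbind(X, v5 = X[, 1] + X[, 2] + rnorm(n, sd = 0.02))
  keptDep <- vifSelect(Xdep, threshold = 10)
  expect_true(all(vifValues(Xdep[, keptDep]) < 10))
  expect_error(vifSelect(matrix(rnorm(6), 2, 3,
                                dimnames = list(NULL, c("a", "b", "c")))),
               "more samples")
})

test_that("Cox fit recovers a true hazard ratio of 2 and nulls cover 1", {
  hrs <- nullCover <- numeric(10)
  for (s in 1:10) {
    x <- blockExpr(nBlock = 5, nNoise = 5, n = 300, rho = 0,
                   seed = 700 + s)
    spec <- survivalEffectSpec(riskGenes = rownames(x)[1],
                               logHazardPerUnit = log(2),
                               censoringRate = 0.2)
    surv <- simulateSurvival(x, spec, seed = 800 + s)
    ## covariate = the standardized risk gene; plus an unrelated null gene
    xs <- x
    xs[1, ] <- as.numeric(scale(x[1, ]))
    fit <- fitCoxRisk(rownames(x)[c(1, 7)], xs, surv)
    hrs[s] <- fit@hazardRatios[1]
    ci <- summary(fit@fit)$conf.int
    nullCover[s] <- ci[2, "lower .95"] <= 1 && ci[2, "upper .95"] >= 1
  }
  expect_gte(sum(hrs >= 1.7 & hrs <= 2.35), 8)
  expect_gte(mean(nullCover), 0.9)
})

test_that("c-index is 1 when risk perfectly orders uncensored times", {
  n <- 30
  surv <- data.frame(sample = sprintf("p%02d", 1:n),
                     time = seq(1000, 100, length.out = n), event = 1L)
  x <- matrix(seq_len(n), 1, n,
              dimnames = list("riskgene", surv$sample))
  fit <- suppressWarnings(fitCoxRisk("riskgene", x, surv))
  expect_equal(unname(fit@cIndex), 1)
  expect_equal(unname(fit@hazardRatios), unname(exp(fit@coefficients)))
  expect_error(fitCoxRisk("riskgene", x,
                          transform(surv, event = 0L)), "no events")
})

test_that("quartile stratification follows the Q1/Q3 rule exactly", {
  s <- quartileStrata(1:8)
  expect_equal(as.vector(table(s)), c(2L, 4L, 2L))
  ## identical scores all medium
  sFlat <- quartileStrata(rep(3, 10))
  expect_true(all(sFlat == "medium"))
  ## always a partition
  set.seed(9)
  r <- runif(37)
  s2 <- quartileStrata(r)
  expect_equal(length(s2), 37)
  expect_false(anyNA(s2))
})

test_that("a planted strong effect yields ordered, separated risk strata", {
  x <- blockExpr(nBlock = 5, nNoise = 5, n = 300, rho = 0, seed = 900)
  spec <- survivalEffectSpec(riskGenes = rownames(x)[1:3],
                             logHazardPerUnit = log(3),
                             censoringRate = 0.2)
  surv <- simulateSurvival(x, spec, seed = 901)
  fit <- fitCoxRisk(rownames(x)[1:3], x, surv)
  strata <- stratifyRisk(fit, x)
  expect_equal(length(strata), 300)
  d <- data.frame(time = surv$time, event = surv$event,
                  strata = strata[surv$sample])
  sd3 <- survival::survdiff(survival::Surv(time, event) ~ strata,
                            data = d)
  expect_lt(1 - pchisq(sd3$chisq, df = 2), 0.05)
  ## median survival ordered low > medium > high risk
  med <- summary(survival::survfit(survival::Surv(time, event) ~ strata,
                                   data = d))$table[, "median"]
  expect_true(med[1] > med[2] && med[2] > med[3])
})

test_that("the linear SVM separates planted outset genes and not noise", {
  set.seed(21)
  n1 <- 30; n2 <- 30
  labels <- factor(rep(c("normal", "I"), c(n1, n2)),
                   levels = c("normal", "I"))
  ## 3-SD shift on 5 genes: essentially separable
  x <- cbind(matrix(rnorm(5 * n1), 5), matrix(rnorm(5 * n2, 3), 5))
  rownames(x) <- paste0("g", 1:5)
  colnames(x) <- sprintf("s%02d", 1:(n1 + n2))
  res <- svmValidate(x, labels, seed = 4)
  expect_gte(res$accuracy, 0.95)
  ## stratified folds: class ratio within one sample of global
  for (f in 1:5) {
    tab <- table(labels[res$fold == f])
    expect_lte(abs(tab[["normal"]] - tab[["I"]]), 1)
  }
  ## permuted labels: chance-level accuracy
  accNull <- vapply(1:5, function(s) {
    set.seed(30 + s)
    svmValidate(x, sample(labels), seed = s)$accuracy
  }, 0)
  expect_gte(median(accNull), 0.35)
  expect_lte(median(accNull), 0.65)
  small <- factor(rep(c("normal", "I"), c(4, 3)),
                  levels = c("normal", "I"))
  expect_error(svmValidate(x[, 1:7], small, seed = 1), "at least 5")
})
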