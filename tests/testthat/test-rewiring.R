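## Build a ThresholdedNetwork directly from an edge list.
mkThr <- function(condition, edges, genes, cutoff = 0.7) {
  e <- if (length(edges)) do.call(rbind, lapply(edges, function(x)
    data.frame(geneA = min(x[[1]], x[[2]]), geneB = max(x[[1]], x[[2]]),
               r = as.numeric(x[[3]])))) else
    data.frame(geneA = character(0), geneB = character(0),
               r = numeric(0))
  e <- e[order(e$geneA, e$geneB), , drop = FALSE]
  rownames(e) <- NULL
  new("ThresholdedNetwork", condition = condition, edges = e,
      genes = genes, cutoff = cutoff)
}

test_that("conditionNetwork keeps only |r| >= cutoff with signs retained", {
  set.seed(2)
  n <- 50
  base <- rnorm(n)
  x <- rbind(a = base,
             b = 0.9 * base + sqrt(1 - 0.81) * rnorm(n),  # r ~ 0.9
             c = -base,                                    # r = -1 with a
             d = rnorm(n),                                 # unrelated
             dup = base)                                   # r = 1 with a
  colnames(x) <- sprintf("s%02d", 1:n)
  net <- conditionNetwork(x, colnames(x), rownames(x), "I", cutoff = 0.7)
  e <- net@edges
  key <- paste(e$geneA, e$geneB)
  expect_true("a c" %in% key)
  expect_lt(e$r[key == "a c"], 0)       # negative edge present, signed
  expect_true("a dup" %in% key)
  expect_equal(e$r[key == "a dup"], 1)
  expect_false(any(e$geneA == "d" | e$geneB == "d"))  # weak pairs absent
  expect_true(all(abs(e$r) >= 0.7))
  ## a pair at r about 0.65 is absent
  x2 <- rbind(p = base, q = 0.65 * scale(base)[, 1] +
                sqrt(1 - 0.65^2) * scale(rnorm(n))[, 1])
  colnames(x2) <- colnames(x)
  r <- cor(x2["p", ], x2["q", ])
  net2 <- conditionNetwork(x2, colnames(x2), rownames(x2), "I")
  expect_equal(nrow(net2@edges), as.integer(abs(r) >= 0.7))
  ## zero-variance gene excluded with a warning
  x3 <- rbind(x, flat = rep(1, n))
  expect_warning(net3 <- conditionNetwork(x3, colnames(x3), rownames(x3),
                                          "I"), "flat")
  expect_false("flat" %in% net3@genes)
})

test_that("edge changes are classified gain, loss and reversed", {
  genes <- c("a", "b", "c", "d")
  early <- mkThr("I", list(list("a", "b", 0.9),   # will be lost
                           list("a", "c", 0.8),   # will reverse
                           list("b", "c", 0.75)), # unchanged
                 genes)
  late <- mkThr("II", list(list("a", "c", -0.8),
                           list("b", "c", 0.8),
                           list("c", "d", 0.85)), # gained
                genes)
  rw <- classifyRewiring(early, late)
  e <- rw@edges
  cls <- setNames(e$class, paste(e$geneA, e$geneB))
  expect_identical(unname(cls["a b"]), "loss")
  expect_identical(unname(cls["a c"]), "reversed")
  expect_identical(unname(cls["c d"]), "gain")
  expect_false("b c" %in% names(cls))   # unchanged edge omitted
  expect_equal(nrow(e), 3)
  expect_error(classifyRewiring(early, mkThr("II", list(), genes,
                                             cutoff = 0.8)), "cutoff")
})

test_that("self-comparison is empty and swap maps gains to losses", {
  set.seed(5)
  x <- matrix(rnorm(20 * 30), 20, 30,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("s%02d", 1:30)))
  netA <- conditionNetwork(x, colnames(x), rownames(x), "I",
                           cutoff = 0.3)
  expect_equal(nrow(classifyRewiring(netA, netA)@edges), 0)
  y <- matrix(rnorm(20 * 30), 20, 30, dimnames = dimnames(x))
  netB <- conditionNetwork(y, colnames(y), rownames(y), "II",
                           cutoff = 0.3)
  fwd <- classifyRewiring(netA, netB)@edges
  netA2 <- netA; netA2@condition <- "II"
  netB2 <- netB; netB2@condition <- "I"
  bwd <- classifyRewiring(netB2, netA2)@edges
  keyCls <- function(e) setNames(e$class, paste(e$geneA, e$geneB))
  f <- keyCls(fwd); b <- keyCls(bwd)
  expect_setequal(names(f), names(b))
  expect_true(all(b[names(f)[f == "gain"]] == "loss"))
  expect_true(all(b[names(f)[f == "loss"]] == "gain"))
  expect_true(all(b[names(f)[f == "reversed"]] == "reversed"))
})

test_that("hub extraction ranks by changed-edge degree with stable ties", {
  genes <- c("hub", letters[1:6])
  star <- mkThr("I", lapply(letters[1:6], function(g)
    list("hub", g, 0.9)), genes)
  none <- mkThr("II", list(), genes)
  rw <- classifyRewiring(star, none)
  expect_identical(hubNodes(rw, 0.1), "hub")
  ## all genes with exactly one changed edge: identifier order decides
  chain <- mkThr("I", list(list("a", "b", 0.8), list("c", "d", 0.8),
                           list("e", "f", 0.8)), letters[1:6])
  rw2 <- classifyRewiring(chain, mkThr("II", list(), letters[1:6]))
  expect_identical(hubNodes(rw2, 0.1), "a")  # ceiling(0.6) = 1
  expect_identical(hubNodes(rw2, 0.5), c("a", "b", "c"))
})

test_that("planted hubs are recovered across seeds", {
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 100
    hubGene <- "g01"
    others <- sprintf("g%02d", 2:12)
    ## later condition: hub gains strong edges to 10 partners
    f <- rnorm(n)
    late <- rbind(matrix(rep(f, 11), 11, byrow = TRUE) * 0.95 +
                    0.3 * matrix(rnorm(11 * n), 11),
                  matrix(rnorm(n), 1))
    rownames(late) <- c(hubGene, others)
    colnames(late) <- sprintf("s%03d", 1:n)
    early <- matrix(rnorm(12 * n), 12, n, dimnames = dimnames(late))
    netE <- conditionNetwork(early, colnames(early), rownames(early),
                             "III")
    netL <- conditionNetwork(late, colnames(late), rownames(late), "IV")
    rw <- classifyRewiring(netE, netL)
    expect_true(hubGene %in% rw@hubs)
  }
})

test_that("planted gains and losses are called with perfect accuracy", {
  hits <- vapply(1:10, function(s) {
    ## module co-expressed only in the later condition: its pairs are
    ## gains; a second module co-expressed only earlier: losses
    mods <- list(
      plantedModule(sprintf("gene_%04d", 1:10),
                    c(normal = 0, I = 0.9, II = 0, III = 0, IV = 0)),
      plantedModule(sprintf("gene_%04d", 11:20),
                    c(normal = 0.9, I = 0, II = 0, III = 0, IV = 0)))
    cfg <- simulationConfig(nGenes = 100,
                            nSamplesPerCondition = c(normal = 100,
                                                     I = 100, II = 3,
                                                     III = 3, IV = 3),
                            modules = mods, seed = 50 + s)
    sim <- simulateStageData(cfg)
    expr <- log2(sweep(sim$counts, 2, colSums(sim$counts), "/") * 1e6 + 1)
    genes <- rownames(expr)
    sN <- sim$design$sample[sim$design$condition == "normal"]
    sI <- sim$design$sample[sim$design$condition == "I"]
    netN <- conditionNetwork(expr, sN, genes, "normal", cutoff = 0.7)
    netI <- conditionNetwork(expr, sI, genes, "I", cutoff = 0.7)
    rw <- classifyRewiring(netN, netI)@edges
    called <- paste(rw$geneA, rw$geneB, rw$class)
    expGain <- apply(combn(sprintf("gene_%04d", 1:10), 2), 2,
                     function(p) paste(p[1], p[2], "gain"))
    expLoss <- apply(combn(sprintf("gene_%04d", 11:20), 2), 2,
                     function(p) paste(p[1], p[2], "loss"))
    setequal(called, c(expGain, expLoss))
  }, TRUE)
  expect_true(all(hits))
})

test_that("five-index biomarker ranking orders genes as designed", {
  out <- rankProgressionBiomarkers(
    genes = c("allFive", "examplarA", "examplarB", "nothing", "sf3like"),
    prognostic = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    trendClass = c("ascending", "descending", "none", "none",
                   "ascending"),
    hubTransitions = c(1L, 1L, 0L, 0L, 1L),
    novel = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    rewiredTransitions = c(2L, 2L, 1L, 0L, 3L))
  expect_identical(out$gene[1], "allFive")
  ## a gene with trend + hub + 2 rewired transitions outranks one with
  ## neither trend nor hub and a single transition
  expect_lt(which(out$gene == "examplarA"),
            which(out$gene == "examplarB"))
  expect_identical(out$gene[nrow(out)], "nothing")
  expect_equal(out$nIndices[out$gene == "allFive"], 5)
  expect_equal(out$nIndices[out$gene == "nothing"], 0)
  ## tie on indices: more re-wired transitions wins
  expect_lt(which(out$gene == "sf3like"),
            which(out$gene == "examplarB"))
})
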