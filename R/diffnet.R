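## Per-condition correlation networks, the differential co-expression
## dissimilarity between two sample groups, and module extraction by
## average-linkage hierarchical clustering with a hybrid (PAM-like)
## assignment stage.

#' Pearson co-expression network over a sample subset
#'
#' @param expr Normalized expression matrix (genes x samples).
#' @param samples Sample identifiers to use (>= 3).
#' @param condition Label stored with the network (default "pooled").
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
correlationNetwork <- function(expr, samples, condition = "pooled") {
  expr <- as.matrix(expr)
  missing <- setdiff(samples, colnames(expr))
  if (length(missing))
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- expr[, samples, drop = FALSE]
  if (ncol(sub) < 3) stop("need at least 3 samples to correlate")
  v <- apply(sub, 1, var)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(sub)[v == 0], collapse = ", "))
  a <- cor(t(sub))
  a[a > 1] <- 1; a[a < -1] <- -1
  diag(a) <- 1
  methods::new("CoexpressionNetwork", adjacency = a,
               nSamples = ncol(sub), condition = condition)
}

#' Differential co-expression dissimilarity between two networks
#'
#' For each gene pair the signed-squared correlations of the two networks
#' are contrasted:
#' \deqn{d_{ij} = \left(\frac{|sign(c^A_{ij}) (c^A_{ij})^2 -
#'   sign(c^B_{ij}) (c^B_{ij})^2|}{2}\right)^{\beta/2}.}
#' With \code{useTom = TRUE} the result is passed through a weighted
#' topological-overlap transform and returned as \code{1 - TOM}, which
#' sharpens block structure by comparing shared neighbourhoods; a
#' completely unchanged pair of networks (all \eqn{d_{ij} = 0}) is
#' returned as the zero matrix, i.e. no re-wiring means no dissimilarity.
#'
#' @param netA,netB \linkS4class{CoexpressionNetwork}s over the same genes
#'   in the same order.
#' @param beta Even positive soft-threshold exponent (default 6).
#' @param useTom Apply the topological-overlap transform (default TRUE).
#' @return A \linkS4class{DiffMatrix}.
#' @export
differentialDissimilarity <- function(netA, netB, beta = 6L,
                                      useTom = TRUE) {
  beta <- as.integer(beta)
  if (beta < 2L || beta %% 2L != 0L)
    stop("beta must be a positive even integer")
  a <- netA@adjacency; b <- netB@adjacency
  if (!identical(rownames(a), rownames(b)))
    stop("networks must share an identical, identically ordered gene set")
  d0 <- (abs(a * abs(a) - b * abs(b)) / 2)^(beta / 2)
  diag(d0) <- 0
  d <- if (useTom && max(d0) > 0) tomDissimilarity(d0) else d0
  d[d < 0] <- 0; d[d > 1] <- 1
  d <- (d + t(d)) / 2
  diag(d) <- 0
  methods::new("DiffMatrix", dissimilarity = d, beta = beta,
               useTom = useTom,
               conditions = c(netA@condition, netB@condition))
}

## Weighted topological overlap dissimilarity of a nonnegative adjacency
## (diag 0, entries in [0,1]): 1 - (L_ij + a_ij) / (min(k_i,k_j) + 1 - a_ij).
tomDissimilarity <- function(a) {
  k <- rowSums(a)
  L <- a %*% a
  minK <- outer(k, k, pmin)
  tom <- (L + a) / (minK + 1 - a)
  diag(tom) <- 1
  1 - tom
}

#' Extract co-expression modules from a differential dissimilarity
#'
#' Average-linkage hierarchical clustering of the dissimilarity followed
#' by a hybrid assignment: (1) the dendrogram is cut at \code{cutHeight}
#' and branches of at least \code{minModuleSize} genes become module
#' cores; (2) each unassigned gene is attached, PAM-like, to the nearest
#' core provided its mean dissimilarity to that core is within the core's
#' own spread (mean + 2.5 sd of the core's pairwise dissimilarities);
#' (3) cores whose medoids are closer than \code{mergeHeight} are merged;
#' (4) modules smaller than \code{minModuleSize} are dissolved. Labels are
#' \code{module_1}, \code{module_2}, ... by decreasing size, remaining
#' genes are \code{"unassigned"}.
#'
#' @param diff A \linkS4class{DiffMatrix}.
#' @param mergeHeight Medoid-dissimilarity threshold below which two
#'   modules are merged (default 0.2).
#' @param minModuleSize Smallest reported module (default 10).
#' @param cutHeight Static tree-cut height on the dissimilarity scale
#'   (default 0.99, suited to the \code{1 - TOM} scale where unrelated
#'   genes sit close to 1).
#' @return A \linkS4class{ModulePartition}.
#' @export
detectModules <- function(diff, mergeHeight = 0.2, minModuleSize = 10L,
                          cutHeight = 0.99) {
  d <- diff@dissimilarity
  genes <- rownames(d)
  if (length(genes) < 2 * minModuleSize)
    stop("need at least 2 * minModuleSize genes")
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = min(cutHeight, max(hc$height)))
  sizes <- table(cl)
  coreIds <- as.integer(names(sizes)[sizes >= minModuleSize])
  lab <- rep(NA_integer_, length(genes))
  names(lab) <- genes
  for (cid in coreIds) lab[cl == cid] <- cid

  if (length(coreIds)) {
    ## PAM-like stage: attach leftover genes to a compatible nearest core
    coreStats <- lapply(coreIds, function(cid) {
      g <- genes[which(cl == cid)]
      dd <- d[g, g][upper.tri(d[g, g])]
      list(genes = g, mean = mean(dd), sd = sd(dd))
    })
    names(coreStats) <- coreIds
    for (g in genes[is.na(lab)]) {
      avg <- vapply(coreStats, function(cs) mean(d[g, cs$genes]), 0)
      best <- which.min(avg)
      cs <- coreStats[[best]]
      if (avg[best] <= cs$mean + 2.5 * cs$sd)
        lab[g] <- coreIds[best]
    }
    ## merge cores whose medoids are closer than mergeHeight
    repeat {
      ids <- sort(unique(lab[!is.na(lab)]))
      if (length(ids) < 2) break
      med <- vapply(ids, function(cid) {
        g <- names(lab)[!is.na(lab) & lab == cid]
        g[which.min(rowSums(d[g, g, drop = FALSE]))]
      }, "")
      dm <- d[med, med, drop = FALSE]
      diag(dm) <- Inf
      if (min(dm) >= mergeHeight) break
      ij <- which(dm == min(dm), arr.ind = TRUE)[1, ]
      lab[!is.na(lab) & lab == ids[ij[2]]] <- ids[ij[1]]
    }
  }
  ## dissolve undersized modules, label by decreasing size
  ids <- sort(unique(lab[!is.na(lab)]))
  for (cid in ids)
    if (sum(lab == cid, na.rm = TRUE) < minModuleSize)
      lab[!is.na(lab) & lab == cid] <- NA_integer_
  ids <- sort(unique(lab[!is.na(lab)]))
  out <- rep("unassigned", length(genes))
  names(out) <- genes
  if (length(ids)) {
    sz <- vapply(ids, function(cid) sum(lab == cid, na.rm = TRUE), 0L)
    ord <- ids[order(-sz, ids)]
    for (k in seq_along(ord))
      out[!is.na(lab) & lab == ord[k]] <- paste0("module_", k)
  }
  methods::new("ModulePartition", labels = out)
}
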