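## Prognostic-gene detection, stage-trend classification, VIF-pruned Cox
## proportional-hazards risk modelling, quartile risk stratification and
## the linear-SVM sanity check for the outset-cancer gene group.

#' Median-split Kaplan-Meier log-rank test
#'
#' Splits patients at the median expression of one gene (values equal to
#' the median go to the "Low" group), compares the two KM curves with the
#' two-sample log-rank test, and flags the gene prognostic at p < 0.05.
#'
#' @param exprGene Named numeric vector of one gene's expression, names =
#'   samples of the survival table.
#' @param surv data.frame(sample, time, event).
#' @return List: \code{p}, \code{statistic}, \code{group} (factor
#'   Low/High), \code{prognostic}, \code{fit} (a \code{survfit} for the
#'   two curves).
#' @export
kmLogrank <- function(exprGene, surv) {
  x <- exprGene[surv$sample]
  if (anyNA(x)) stop("expression missing for some patients")
  grp <- factor(ifelse(x > median(x), "High", "Low"),
                levels = c("Low", "High"))
  if (any(table(grp) < 2))
    stop("median split leaves fewer than 2 patients in a group")
  d <- data.frame(time = surv$time, event = surv$event, group = grp)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  p <- 1 - pchisq(sd_$chisq, df = 1)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  list(p = p, statistic = sd_$chisq, group = grp,
       prognostic = p < 0.05, fit = fit)
}

## Dunn's rank-based post-hoc z tests after Kruskal-Wallis,
## with a tie correction on the pooled ranks.
dunnPosthoc <- function(x, g) {
  g <- droplevels(factor(g))
  r <- rank(x)
  N <- length(x)
  tieTab <- table(r)
  tieCorr <- sum(tieTab^3 - tieTab) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- table(g)
  lv <- levels(g)
  out <- data.frame()
  for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1):length(lv)) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) *
               (1 / n[[lv[i]]] + 1 / n[[lv[j]]]))
    z <- (rbar[[lv[i]]] - rbar[[lv[j]]]) / se
    out <- rbind(out, data.frame(groupA = lv[i], groupB = lv[j], z = z,
                                 p = 2 * pnorm(-abs(z))))
  }
  out$pAdj <- p.adjust(out$p, method = "BH")
  out
}

#' Classify a gene's expression trend across stages
#'
#' Kruskal-Wallis across stages I--IV with Dunn post-hoc comparisons
#' (Benjamini-Hochberg adjusted); per-condition Shapiro-Wilk normality
#' p-values are recorded. A gene is \emph{ascending} when the
#' Kruskal-Wallis p is below 0.05, the stage medians are monotone
#' non-decreasing from I to IV and at least one adjusted pairwise p is
#' below 0.05; \emph{descending} is symmetric. A gene is
#' \emph{outset-cancer} when it has no monotone stage trend but shifts
#' between normal tissue and stage I (two-sample t-test p < 0.05).
#' Otherwise the call is \emph{none}.
#'
#' @param exprGene Named numeric vector over all samples.
#' @param design data.frame(sample, condition) covering all five
#'   conditions with >= 3 samples each.
#' @return List: \code{class}, \code{kwP}, \code{posthoc} (Dunn table),
#'   \code{outsetP}, \code{shapiroP}, \code{stageMedians}.
#' @export
classifyTrends <- function(exprGene, design) {
  cond <- checkConditions(design$condition)
  if (any(table(cond) < 3))
    stop("every condition needs at least 3 samples; missing/short: ",
         paste(names(which(table(cond) < 3)), collapse = ", "))
  x <- exprGene[design$sample]
  if (anyNA(x)) stop("expression missing for some samples")
  stages <- c("I", "II", "III", "IV")
  inStage <- as.character(cond) %in% stages
  gs <- factor(as.character(cond)[inStage], levels = stages)
  xs <- x[inStage]

  shapiroP <- vapply(CONDITION_LEVELS, function(cc) {
    xi <- x[as.character(cond) == cc]
    if (length(unique(xi)) < 3) return(NA_real_)
    shapiro.test(xi)$p.value
  }, 0)
  kw <- kruskal.test(xs, gs)
  posthoc <- dunnPosthoc(xs, gs)
  med <- tapply(xs, gs, median)
  anySig <- any(posthoc$pAdj < 0.05)
  up <- all(diff(med) >= 0) && any(diff(med) > 0)
  down <- all(diff(med) <= 0) && any(diff(med) < 0)
  tt <- t.test(x[as.character(cond) == "normal"],
               x[as.character(cond) == "I"])
  cls <- if (kw$p.value < 0.05 && anySig && up) "ascending"
  else if (kw$p.value < 0.05 && anySig && down) "descending"
  else if (tt$p.value < 0.05) "outset-cancer"
  else "none"
  list(class = cls, kwP = kw$p.value, posthoc = posthoc,
       outsetP = tt$p.value, shapiroP = shapiroP, stageMedians = med)
}

#' Iterative variance-inflation-factor pruning
#'
#' Repeatedly computes each covariate's VIF \eqn{1/(1-R^2)} (from the
#' regression of that covariate on all remaining ones) and drops the
#' covariate with the largest VIF while any VIF is at or above the
#' threshold. Perfect collinearity (\eqn{R^2 = 1}) counts as infinite
#' VIF and is dropped first. Column order is preserved in the output.
#'
#' @param covariateMatrix Numeric matrix, samples x covariates, with
#'   column names.
#' @param threshold VIF threshold (default 10).
#' @return Character vector of surviving covariate names.
#' @export
vifSelect <- function(covariateMatrix, threshold = 10) {
  X <- as.matrix(covariateMatrix)
  if (ncol(X) < 2) return(colnames(X))
  if (nrow(X) <= ncol(X))
    stop("need more samples than covariates for VIF estimation")
  keep <- colnames(X)
  repeat {
    if (length(keep) < 2) break
    v <- vapply(keep, function(k) {
      r2 <- suppressWarnings(summary(
        lm(X[, k] ~ X[, setdiff(keep, k), drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, 0)
    if (max(v) < threshold) break
    keep <- setdiff(keep, keep[which.max(v)])
  }
  keep
}

#' Compute covariate VIFs
#'
#' @param covariateMatrix Numeric matrix, samples x covariates.
#' @return Named numeric vector of VIFs.
#' @export
vifValues <- function(covariateMatrix) {
  X <- as.matrix(covariateMatrix)
  vapply(colnames(X), function(k) {
    r2 <- suppressWarnings(summary(
      lm(X[, k] ~ X[, setdiff(colnames(X), k), drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

#' Fit the proportional-hazards risk model
#'
#' Cox PH fit (Efron handling of tied event times) of survival on the
#' selected gene covariates; reports hazard ratios, the global
#' likelihood-ratio p-value, Harrell's c-index on the fitting cohort, and
#' the Q1/Q3 risk-score thresholds used for stratification.
#'
#' @param selected Gene covariates to enter the model.
#' @param expr Expression matrix (genes x samples).
#' @param surv data.frame(sample, time, event) with >= 1 event.
#' @return A \linkS4class{RiskModel}.
#' @export
fitCoxRisk <- function(selected, expr, surv) {
  if (!length(selected)) stop("no covariates selected")
  if (sum(surv$event) < 1) stop("no events in the survival table")
  X <- t(expr[selected, surv$sample, drop = FALSE])
  d <- data.frame(time = surv$time, event = surv$event, X,
                  check.names = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", selected),
                                       collapse = " + ")))
  fit <- tryCatch(survival::coxph(fml, data = d, ties = "efron"),
                  error = function(e)
                    stop("Cox model failed to converge: ",
                         conditionMessage(e)))
  sm <- summary(fit)
  cf <- setNames(coef(fit), selected)
  risk <- as.numeric(exp(X %*% cf))
  q <- quantile(risk, c(0.25, 0.75))
  methods::new("RiskModel", covariates = selected, coefficients = cf,
               hazardRatios = exp(cf),
               lrTestP = unname(sm$logtest["pvalue"]),
               cIndex = unname(sm$concordance["C"]),
               strataThresholds = unname(q), fit = fit)
}

#' Quartile risk strata
#'
#' Patients below the first quartile of risk are low risk, above the
#' third quartile high risk, all others (both quartiles inclusive)
#' medium; identical scores therefore all land in the medium stratum.
#'
#' @param risk Numeric risk scores.
#' @param thresholds Optional (Q1, Q3); computed from \code{risk} when
#'   missing.
#' @return Factor with levels low/medium/high.
#' @export
quartileStrata <- function(risk, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- quantile(risk, c(0.25, 0.75))
  factor(ifelse(risk < thresholds[1], "low",
                ifelse(risk > thresholds[2], "high", "medium")),
         levels = c("low", "medium", "high"))
}

#' Per-patient risk scores of a fitted model
#'
#' \eqn{\exp(\beta' x)} over the model's covariates.
#'
#' @param model A \linkS4class{RiskModel}.
#' @param expr Expression matrix (genes x samples).
#' @return Named numeric vector of risk scores.
#' @export
riskScores <- function(model, expr) {
  X <- t(expr[model@covariates, , drop = FALSE])
  setNames(as.numeric(exp(X %*% model@coefficients)), rownames(X))
}

#' Stratify patients by modelled risk
#'
#' Applies the model's fitting-cohort Q1/Q3 thresholds to the patients'
#' risk scores.
#'
#' @param model A \linkS4class{RiskModel}.
#' @param expr Expression matrix (genes x samples).
#' @return Named factor low/medium/high per patient.
#' @export
stratifyRisk <- function(model, expr) {
  r <- riskScores(model, expr)
  setNames(quartileStrata(r, model@strataThresholds), names(r))
}

#' Linear-SVM check of the outset-cancer gene group
#'
#' Five-fold stratified cross-validation of a linear-kernel SVM
#' separating two classes (e.g. normal vs stage I) on the expression of
#' the outset genes; reports fold-averaged accuracy, precision and
#' specificity (positive class = second factor level).
#'
#' @param expr Expression matrix restricted to the outset genes
#'   (genes x samples).
#' @param labels Factor of two classes, one per sample, each with >= 5
#'   samples.
#' @param seed Integer seed for the fold assignment.
#' @param folds Number of folds (default 5).
#' @return List: \code{accuracy}, \code{precision}, \code{specificity},
#'   \code{fold} (per-sample fold ids).
#' @export
svmValidate <- function(expr, labels, seed = 1L, folds = 5L) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("exactly two classes required")
  if (any(table(labels) < folds))
    stop("each class needs at least ", folds, " samples")
  X <- t(as.matrix(expr))
  pos <- levels(labels)[2]
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    acc <- prec <- spec <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      m <- e1071::svm(X[tr, , drop = FALSE], labels[tr],
                      kernel = "linear", scale = FALSE)
      pr <- predict(m, X[!tr, , drop = FALSE])
      truth <- labels[!tr]
      tp <- sum(pr == pos & truth == pos)
      fp <- sum(pr == pos & truth != pos)
      tn <- sum(pr != pos & truth != pos)
      acc[f] <- mean(pr == truth)
      prec[f] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      spec[f] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    }
    list(accuracy = mean(acc), precision = mean(prec, na.rm = TRUE),
         specificity = mean(spec, na.rm = TRUE), fold = fold)
  })
}
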