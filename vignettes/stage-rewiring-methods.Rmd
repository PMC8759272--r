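---
title: "Stage-specific co-expression re-wiring: models and methods"
author: "stageRewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-specific co-expression re-wiring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageRewire)
```

## The scientific problem

Tumour progression is usually studied through differential expression,
but genes can change their *relationships* — which partners they are
co-expressed with — without changing their mean expression at all. This
package implements a topological view of progression for staged cancer
cohorts (the motivating system is ER-positive breast cancer with normal
tissue and tumour stages I–IV): per-stage differential co-expression
networks expose gene modules whose correlation structure is specific to
one stage, a composite score picks the disease-relevant ones, survival
modelling identifies prognostic genes among them, and an edge-level
comparison of consecutive stages classifies every strong co-expression
change as a *gain*, *loss* or *reversal*.

## Differential networks and module extraction

For each stage $s$ the cohort is split into the stage's samples and all
remaining samples, and Pearson adjacency matrices $c^{(s)}$ and
$c^{(\bar s)}$ are computed on normalized expression. The differential
dissimilarity of genes $i,j$ is

$$d_{ij} = \left( \frac{\left| \operatorname{sign}(c^{(s)}_{ij})\,
(c^{(s)}_{ij})^2 - \operatorname{sign}(c^{(\bar s)}_{ij})\,
(c^{(\bar s)}_{ij})^2 \right|}{2} \right)^{\beta/2},$$

with $\beta = 6$ (even, configurable). Squaring with the sign retained
emphasises strong correlations while treating a change from $+0.8$ to
$-0.8$ as maximal re-wiring. By default $d$ is passed through a weighted
topological-overlap transform and clustering operates on $1 -
\mathrm{TOM}(d)$, which compares shared neighbourhoods and sharpens
block structure; when the two networks are identical ($d \equiv 0$) the
dissimilarity is defined as zero — no re-wiring, no differential signal.

Modules are extracted by average-linkage hierarchical clustering with a
hybrid assignment: a static cut at `cutHeight` (default 0.99, matched to
the $1-\mathrm{TOM}$ scale on which unrelated genes sit near 1) yields
module cores of at least `minModuleSize` (default 10) genes; remaining
genes are attached PAM-like to the nearest core only if their mean
dissimilarity to it lies within the core's own spread (mean + 2.5 sd of
its pairwise dissimilarities); cores whose medoids are closer than
`mergeHeight` (default 0.2) are merged. Linkage is a free choice in this
design; average linkage is used because the dissimilarities are bounded
and blockwise-homogeneous. Labels are `module_1, module_2, ...` by
decreasing size — deterministic and self-describing, where colour names
would be presentation only.

The cohort split per stage is stage-vs-rest. Contrasting each stage
against all remaining samples (rather than against normal only) makes
the four differential networks directly comparable and is the only
two-group reading that yields one network per stage.

## Preprocessing

The filter chain is fixed: remove genes with missing values or all-zero
counts; remove genes whose *mean* CPM across samples falls below 0.5
(mean aggregation is the simplest rule monotone in expression; a
per-sample rule would couple the filter to cohort composition); remove
the lowest quartile of the coefficient of variation (computed on the
CPM scale; ties broken by gene identifier so the result is
deterministic); TMM-normalize (30%/5% trimming, upper-quartile
reference, factors geometric-mean-normalized to 1) and express the data
as $\log_2(\mathrm{CPM} + 1)$ on effective library sizes; finally drop
genes with low *scaled connectivity*

$$k_i = \frac{1}{G-1} \sum_{j \ne i} |r_{ij}| < 0.1$$

computed on the pooled-condition correlation matrix. The raw
connectivity sum grows linearly with the number of genes, which would
make a fixed 0.1 cutoff meaningless across datasets; dividing by $G-1$
makes the threshold size-invariant. Unsigned $|r|$ is used because
connectivity here measures interaction magnitude, not direction.

## Stage specificity: preservation statistics

How specific a module is to its stage is measured by how poorly the
module's structure in the stage network is predicted by the rest-cohort
network. Four statistics are computed per module — two density
statistics (mean within-module correlation and mean absolute adjacency
in the test network) and two connectivity statistics (correlation of
intramodular connectivity between the networks, and correlation of the
within-module correlation vectors). Each is Z-scored against `nPerm`
size-matched random gene sets; `Zsummary` is the mean of the density
and connectivity medians, and `Medianrank` is the median of the
module's observed-statistic ranks across modules (rank 1 = most
preserved). The reference design behind these composites uses twelve
statistics; the four implemented here retain both ingredient families
(density and connectivity) at desk scale, a deliberate reduction.

Two numerical choices matter:

* **Null gene sets are drawn from the whole network**, not only from
  clustered genes. When clustering is good, nearly every clustered gene
  belongs to real structure, so cluster-restricted nulls inherit that
  structure and deflate Z — a perfectly preserved module would score
  `Zsummary` near 5 instead of clearly above 10. Whole-network sampling
  (sizes preserved, draws disjoint within a permutation, pool sorted so
  results are independent of gene input order) is the standard
  construction for preservation statistics.
* **Degenerate statistics are excluded, not zeroed.** If a statistic's
  permutation distribution is a point mass (e.g. both connectivity
  correlations are identically 1 whenever reference and test network
  coincide), it carries no evidence and is dropped from the summary
  rather than pulling it toward zero.

Classification uses the conventional bands: `Zsummary` < 2
stage-specific, within [2, 10] moderately so (boundary ties
deliberately assigned to the moderate class, since the defining
inequalities are open), above 10 not stage-specific. A permutation
non-randomness test reports $p = (1 + \#\{Z^{perm} \le Z^{obs}\}) /
(n_{perm} + 1)$ from the same stored permutation draws.

## Composite module scoring

Per stage, each module $j$ receives

$$\mathrm{SS}_j = \bigl(1 - \mathrm{rescale}(Z_{summary,j})\bigr) +
  \mathrm{rescale}(\mathrm{Medianrank}_j) \in [0, 2],$$

$$\mathrm{BCR}_j = \mathrm{rescale}\bigl(-\log_{10} p^{Fisher}_j\bigr)
  \in [0, 1], \qquad
\mathrm{BCRNCR}_j = \frac{\#\{\text{nc genes reported in cancer}\}}
  {\#\{\text{nc genes in module}\}} \in [0, 1],$$

and the composite $\mathrm{BCSS}_j = \mathrm{SS}_j + \mathrm{BCR}_j +
\mathrm{BCRNCR}_j \in [0, 4]$; the module maximising BCSS is the
stage's selected disease-related specific module (ties: larger module,
then label order). Conventions: min–max rescaling is per stage, because
scores are only ever compared within a stage; a constant vector
rescales to 0.5 so a single-module stage remains scored; the Fisher
test is one-sided for enrichment over the coding genes of the
preprocessed universe (disease-gene lists are protein-coding); the
logarithm base is irrelevant after rescaling; a module with no
non-coding genes scores BCRNCR = 0.

## Survival modelling

Prognostic genes are called by a median-split (ties to the Low group)
two-sample log-rank test at $p < 0.05$, applied across all patients —
the split depends only on ranks, so any monotone transform of
expression gives the same call. Stage trends use Kruskal–Wallis over
stages I–IV with Dunn's rank-based post-hoc comparisons
(Benjamini–Hochberg adjusted; Dunn's test is the natural post-hoc for a
rank-based omnibus) and per-condition Shapiro–Wilk recorded for
reference. *Ascending* requires the omnibus $p < 0.05$, monotone
non-decreasing stage medians and at least one significant adjusted
pairwise comparison — the monotonicity requirement operationalises
"trend", which a bare omnibus test does not; *descending* is symmetric;
*outset-cancer* genes shift between normal and stage I (t-test,
$p < 0.05$) without a monotone stage trend.

The risk model prunes covariates by iterated VIF
($1/(1-R^2)$, threshold 10, perfect collinearity treated as infinite
and dropped first), then fits all survivors in one Cox
proportional-hazards model (Efron tie handling) — VIF first, then a
single joint fit, keeps the selection purely collinearity-driven.
Per-patient risk is $\exp(\beta'x)$; the cohort's Q1/Q3 of risk define
low/medium/high strata (both boundaries inclusive to medium, so
constant risk puts everyone in the medium stratum). Model quality is
reported as the likelihood-ratio p-value and Harrell's c-index on the
fitting cohort. The outset-cancer gene group is sanity-checked by a
five-fold stratified linear-kernel SVM separating normal from stage I.

## Re-wiring classification

Over the prognostic gene set, per-condition networks keep edges with
$|r| \ge 0.7$ (boundary inclusive; unsigned, because negative
associations are associations). Between consecutive conditions
(normal→I→II→III→IV) an edge present only later is a *gain*, only
earlier a *loss*, and present in both with opposite signs *reversed*;
a network compared with itself yields the empty set, and swapping the
two conditions maps gains to losses and fixes reversals. Hubs are the
top 10% (at least one) of changed-edge degree, ties by identifier.
Progression biomarkers are ranked by five booleans — prognostic,
monotone trend, hub anywhere, novelty (an external input flag), and
any re-wiring — with ties broken by the number of re-wired transitions.

## The synthetic cohort generator

The generator emulates the motivating study's design: by default 113
normal, 40 stage-I, 92 stage-II, 55 stage-III and 15 stage-IV samples,
a 300-gene universe with four planted 50-gene modules, each tightly
co-expressed ($\rho = 0.85$) everywhere except its target stage where
co-expression collapses to 0 — re-wiring is planted purely in the
correlation structure, never in the mean, mirroring the observation
that re-wired modules need not be differentially expressed. Latent
log-expression is Gaussian (`noiseSd` 0.6 on the natural-log scale, a
realistic biological coefficient of variation) with a one-factor
equicorrelation construction per module and condition; counts are
Poisson draws around library-size-scaled relative expression with
depths uniform in `librarySizeRange` (default 0.8–1.2 million). The
latent log-normal supplies the overdispersion a negative-binomial
generator would; negative intra-correlations are rejected because an
equicorrelated block of size $k$ is only positive semi-definite for
$\rho \ge -1/(k-1)$. Survival times are exponential with log-hazard
$\beta$ per SD of the standardized mean expression of the risk genes
(default: ten genes of the stage-I module at a hazard ratio of 2);
censoring is independent exponential with its rate tuned to the target
censored fraction (default 20%) — exactly zero censoring when the rate
is 0, approximately the stated fraction otherwise, since an exactly
attained fraction cannot be independent of the event process.
Annotations assign `round(fraction * n)` non-coding, disease
(coding-only) and cancer-reported (non-coding-only) flags by seeded
sampling. One master seed drives everything through fixed offsets
(simulation: seed; annotations: seed+1; survival: seed+2; preservation
for stage $k$: seed+10+$k$; SVM folds: seed+20), so identical
configurations reproduce bit-identically.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: batch and technical
artefacts beyond library depth, isoform structure, negative-binomial
overdispersion per gene, hub-like heterogeneous module topology (module
blocks are equicorrelated, so intramodular connectivity carries no
gene-specific signal), non-proportional hazards, and informative
censoring. One realistic artefact it *does* reproduce is compositional
attenuation: when planted modules occupy a large fraction of the
library, CPM normalization couples all genes to the module factors and
observed correlations sit visibly below the latent $\rho$; fixtures
that assert near-latent correlations use a background-dominated
universe.

## Problem sizes and determinism

The test and acceptance workloads use desk-scale versions of the study
design chosen to finish comfortably on one CPU: module-recovery checks
use 300 genes × 60 samples per condition over 10 seeds; the composite
selection check 20 seeds with 50 permutations; log-rank oracles 10,000
permutation draws at $n = 40$; Cox recovery $n = 300$ with 20%
censoring over 10 seeds; re-wiring recovery $n = 100$ per condition.
The end-to-end pipeline on the full default cohort (315 samples)
completes in well under a minute and reproduces bit-identically under
a fixed seed.

## Known limitations

Preservation Z-scores depend on the statistic set; with only four
statistics the moderate band [2, 10] is wide relative to their
granularity, and modules without connectivity gradients are judged
almost entirely on density. The static-cut-plus-PAM module detector is
tuned to TOM-scale dissimilarities; raw (non-TOM) differential
dissimilarities concentrate near zero and need a user-supplied
`cutHeight`. The SVM check reports fold-averaged metrics only. The
pipeline's per-stage module detection, scoring and survival steps are
pure functions of their inputs, so any single stage can be re-run in
isolation from the report's intermediate objects.
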