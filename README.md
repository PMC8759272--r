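# stageRewire

Differential co-expression ("re-wiring") analysis of cancer progression
across tumour stages, for computational biologists studying staged
cohorts (the motivating design is ER-positive breast cancer: normal
tissue plus stages I–IV with overall-survival follow-up).

Progression signals need not show up as differential expression: genes
can swap, lose or invert their co-expression partners while their means
stay flat. stageRewire makes that topological signal the primary object
of analysis:

1. **Preprocessing** — remove NA/all-zero genes, drop genes with mean
   CPM < 0.5, drop the lowest CV quartile, TMM-normalize to
   log2(CPM+1), and drop genes with scaled connectivity
   k_i = Σ_{j≠i}|r_ij| / (G−1) < 0.1.
2. **Differential networks** — per stage *s*, contrast the stage's
   Pearson adjacency with the rest of the cohort:
   d_ij = ( |sign(c^s_ij)(c^s_ij)² − sign(c^rest_ij)(c^rest_ij)²| / 2 )^(β/2),
   β = 6, followed by a topological-overlap transform; modules are
   extracted by average-linkage hierarchical clustering with a hybrid
   (PAM-like) assignment stage and medoid merging below height 0.2.
3. **Stage specificity** — permutation Zsummary / Medianrank
   preservation statistics of every module (stage network vs rest
   network); Zsummary < 2 is stage-specific, > 10 preserved.
4. **Composite scoring** — per module,
   BCSS = SS + BCR + BCRNCR ∈ [0, 4], where
   SS = (1 − rescale(Zsummary)) + rescale(Medianrank),
   BCR = rescale(−log10 Fisher-enrichment p) against a disease-gene
   list, and BCRNCR is the cancer-reported fraction of the module's
   non-coding genes. The argmax module is the stage's selected
   subnetwork.
5. **Survival** — median-split Kaplan–Meier log-rank prognostic calls;
   ascending / descending / outset-cancer trend classification
   (Kruskal–Wallis + Dunn post-hoc, BH-adjusted); VIF-pruned Cox
   proportional-hazards risk model with exp(β'x) risk scores, Q1/Q3
   risk strata, LR test and Harrell's c-index; linear-SVM check of the
   outset genes.
6. **Re-wiring** — per-condition networks at |r| ≥ 0.7 over the
   prognostic genes; edges classified gain / loss / reversed between
   consecutive conditions, with hub genes and a five-index progression
   biomarker ranking.

A seeded synthetic-cohort generator with planted module re-wiring,
annotations and survival effects makes every step testable against
ground truth.

## Worked example

```r
library(stageRewire)

cfg <- pipelineConfig(simulation = simulationConfig(seed = 1L),
                      nPerm = 50L, seed = 1L)
report <- runPipeline(cfg)
print(report)
#> ReportBundle (seed 1 )
#> genes after preprocessing: 126
#> stage I: selected module_2
#> stage II: selected module_1
#> stage III: selected module_2
#> stage IV: selected module_2
#> prognostic genes: 44 of 125
#> risk model: 44 covariates, c-index = 0.719
#>   transition gain loss reversed
#> 1  normal->I    0  630        0
#> 2      I->II  629    3        0
#> 3    II->III    4    0        0
#> 4    III->IV    0    8        0
```

The default simulation plants four 50-gene modules, each co-expressed
(ρ = 0.85) in every condition except its target stage. Reading the
output: preprocessing keeps 126 of 300 genes (the CV and connectivity
filters are deliberately aggressive); each stage's differential network
yields modules of which the composite score selects one; 44 of the
selected genes are prognostic at log-rank p < 0.05 — the simulation
gives ten stage-I-module genes a true hazard ratio of 2 per SD — and
the VIF-pruned Cox model concords with outcomes at c-index 0.72. The
re-wiring table shows the planted structure: the stage-I module's 630
within-module edges present in normal tissue are *lost* in stage I and
*gained* back in stage II, exactly as planted.

Per-stage score tables live in the report:

```r
report$stages[["I"]]$scores[, c("module","size","ss","bcr","bcrncr","bcss","class")]
#>    module size ss bcr bcrncr bcss              class
#>  module_2   36  2   0  0.444 2.44     stage-specific
#>  module_1   53  0   1  0.333 1.33 not stage-specific
```

`module_2` — the surviving core of the planted stage-I block — has the
minimal Zsummary / maximal Medianrank corner (SS = 2) and wins BCSS
despite `module_1`'s annotation enrichment.

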