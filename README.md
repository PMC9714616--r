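# ptcRiskScreen

Papillary thyroid carcinoma (PTC) is usually indolent, but the subset of
tumors that metastasize to lymph nodes recurs often and carries a much
worse prognosis. A practical way to look for metastasis-risk biomarkers is
a screening funnel over public expression cohorts: find genes that are
strongly and consistently differentially expressed between metastatic PTC
and normal thyroid across several cohorts, keep the ones whose expression
is associated with survival, identify the most interconnected ("core")
genes within that risk set, and finally check the survivors by RT-qPCR in
paired clinical samples.

`ptcRiskScreen` implements that funnel as a tested, reusable R package for
bioinformaticians who want to run or stress-test this class of screen
without depending on web tools. Every stage is an exported function on
S4 objects (the cohort container extends `SummarizedExperiment`), and a
seeded synthetic-cohort generator with planted ground truth lets the whole
pipeline be validated end to end.

## The stages and their statistics

1. **Per-cohort differential expression** (`computeDeg`). For gene *g*
   with log2 expression, the effect is
   `log2FC(g) = mean(tumor) − mean(normal)` with a two-sided Welch t
   p-value. A gene is *up* if `log2FC > 2` and `p < 0.05`, *down* if
   `log2FC < −2` and `p < 0.05` (strict inequalities; both gates
   configurable).
2. **Direction-consistent intersection** (`intersectDegs`). A gene is kept
   only if it is significant *with the same direction in every cohort*;
   genes significant everywhere but with mixed directions are reported as
   conflicted.
3. **Independent-cohort verification** (`verifyDirections`). Each
   intersected gene must be significant with the same direction in a
   larger validation cohort.
4. **Survival screen** (`screenSurvival`). Patients are split at the
   median expression of each gene; the two arms are compared with a
   from-scratch Kaplan–Meier / log-rank machinery
   (`kmEstimator`, `logrankTest`):
   `S(t_k) = Π_{j≤k} (1 − d_j/n_j)` and the 1-df chi-square
   `(O − E)² / V` over pooled event times. Genes with `p < 0.05` form the
   risk set.
5. **Core-gene scoring** (`cumulativeScores`, `rankCoreGenes`). Pairwise
   Pearson `|r|` values within the risk set (tumor samples) are binned to
   points — `|r| < 0.4 → 0`, `0.4–0.6 → 1`, `0.6–0.8 → 2`, `0.8–1.0 → 3`
   — and each gene's points are summed over its partners; the top
   cumulative scores define the core risk genes.
6. **qPCR validation** (`deltaDeltaCt`, `testRelativeExpression`).
   Relative expression in paired tumor/adjacent tissue by the 2^−ΔΔCt
   method, normalized to a housekeeping gene (default ACTB), with a paired
   two-sided t-test on the per-patient ΔCt values.

`runPipeline()` chains all stages from one YAML/list config;
`simulateCohorts()`, `simulateSurvival()`, `simulateCt()` and
`simulateValidationCohort()` generate seeded synthetic inputs with known
planted truth.

## Worked example

```r
library(ptcRiskScreen)
rep <- runPipeline(list(simulate = list(seed = 42)))
print(rep)
```

```
PipelineReport [complete]: stages deg -> intersect -> verify -> survival -> score -> qpcr -> rfs
  DEGs per cohort: synth1=23, synth2=23, synth3=23
  intersection: 8 up, 15 down, 0 conflicted
  risk set (OS-significant): 14 gene(s)
  core genes: gene0049, gene0165, gene0024, gene0128
  qPCR-validated: 14 gene(s)
```

The generator planted 8 upregulated and 15 downregulated genes at
|log2FC| = 4 in three 20-tumor/20-normal cohorts: each per-cohort screen
finds exactly those 23, the direction-consistent intersection recovers the
planted sets with no conflicts, the median-split log-rank filter keeps 14
of them as the OS-associated risk set, and the correlation-bin scoring
ranks the four planted core-module genes on top:

```r
head(rep$score_table[order(-rep$score_table$cumulative), ], 4)
#       gene cumulative rank
#   gene0049          7    1
#   gene0165          7    1
#   gene0024          6    2
#   gene0128          6    2
identical(sort(rep$core_genes), rep$truth$core_module)   # TRUE
```

A cumulative score of 7 means, e.g., three very-strong partners
(3 + 3 points) plus one weak one (1 point) among the other risk genes,
while genes outside the core module score near 0. All 14 risk-set genes
are confirmed by the simulated qPCR stage with fold-change directions
matching the planted truth.

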