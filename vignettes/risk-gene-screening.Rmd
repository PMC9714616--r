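---
title: "Screening PTC metastasis risk genes: methods and design notes"
author: "ptcRiskScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening PTC metastasis risk genes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcRiskScreen)
```

# The screening funnel

`ptcRiskScreen` implements a biomarker screen for papillary thyroid
carcinoma (PTC) lymph-node-metastasis risk genes. The premise: genes that
are strongly and *reproducibly* differentially expressed between
metastatic PTC and normal thyroid across independent cohorts, and whose
expression levels stratify patient survival, are candidate risk factors;
the most strongly inter-correlated members of that risk set ("core risk
genes") are the likeliest to sit in the disease-relevant program (in the
thyroid, iodine handling and hormone synthesis); and a paired-tissue
RT-qPCR check provides orthogonal, assay-level confirmation.

The funnel is strictly nested — each stage filters the previous stage's
output and nothing re-enters:

DEG screen per cohort → direction-consistent intersection →
independent-cohort verification → overall-survival filter (the "risk
set") → correlation-bin core scoring → qPCR validation → optional
relapse-free-survival pass over the validated genes.

# Stage models and assumptions

## Differential expression

Input cohorts are genes × samples matrices of **log2-scale** expression
with tumor/normal labels (as in processed microarray series matrices); a
`log2Transform` flag applies `log2(x + 1)` to linear-scale input. For each
gene the effect is the difference of group means of log2 values (tumor −
normal), i.e. a log2 fold change, with a two-sided Welch t-test p-value.
The Welch test assumes approximate normality of log2 expression within
groups and makes no equal-variance assumption; it is computed vectorized
across genes, and two degenerate cases are fixed by rule rather than
error: both groups constant and equal gives p = 1, both groups constant
but different gives the smallest representable positive p with a warning.

The screening gates are `|log2FC| > 2` and `p < 0.05`, both **strict**
inequalities — a gene exactly at a boundary is not significant. The
p-values are raw by default. An empirical-Bayes moderated test with
multiplicity adjustment would be the modern choice for 20-sample
microarray cohorts; we deliberately expose an unmoderated test with a
`pAdjust = "BH"` option (off by default) because the screen's defining
gate is a raw-p threshold, and because at `|log2FC| > 2` the fold-change
gate, not the p-gate, does almost all the work: with per-gene noise around
0.5 log2 units and 20 samples per group, the gate sits roughly twelve
standard errors from a null gene's expected effect.

## Intersection and verification

A gene enters the common up (down) set only if it is called up (down) in
*every* cohort. Genes significant everywhere with mixed directions are
reported as `conflicted` and excluded from both sets — surfacing, never
silently merging, because a direction flip across platforms usually means
a probe or annotation problem. The intersection is computed over the gene
universe shared by all cohorts; genes missing from any cohort are counted
and set aside. Verification repeats the DEG call in an independent
(typically larger) cohort and confirms a gene only if direction matches
and significance holds; genes absent there are flagged unverifiable
rather than dropped.

## Survival screen

Both the Kaplan–Meier estimator and the two-group log-rank test are
implemented from first principles, since expression-dichotomized log-rank
screening is the analytical core of the survival stage. Conventions:
event ties share a risk set with events counted before censorings at the
same time (standard product-limit convention); the log-rank variance is
the hypergeometric form with the `(n − d)/(n − 1)` tie correction; a
time point contributing fewer than two at-risk subjects is skipped. The
suite checks the estimator against the `survival` package to 1e-10 over
100 random censored datasets and calibrates the log-rank null rejection
rate over 1000 two-group exponential simulations.

The default cutoff is the **median** split: reproducible and assumption
free. A `"scan"` option scans the 0.25–0.75 quantiles and keeps the
minimum p — matching the "best cutoff" behavior of popular survival
portals — but it inflates significance, so it emits an explicit warning
and is never a default. P-values are raw across genes by default (the
screen's gate is a raw `p < 0.05`); BH adjustment is available.

## Core-gene scoring

Within the risk set, pairwise Pearson coefficients are computed over the
**tumor samples** (the disease context in which co-regulation matters;
configurable to normal or all samples). Each `|r|` is binned to points:

| `|r|` | points |
|---|---|
| < 0.4 | 0 |
| 0.4 – 0.6 | 1 |
| 0.6 – 0.8 | 2 |
| 0.8 – 1.0 | 3 |

The published description of such interval scales leaves the endpoints
ambiguous; we fix **left-closed** bins (the last bin closed on both ends),
so 0.4, 0.6 and 0.8 fall upward. The choice is measure-zero for
continuous data and makes the rule deterministic. Negative correlations
score by magnitude. A gene's cumulative score is the sum of its n − 1
pair scores (so at most `3(n − 1)`); genes are dense-ranked descending,
ties sharing a rank and displayed alphabetically, and the top-k ranks
(ties expanding the list, with a flag) define the core genes. A
brute-force double-loop implementation of the same rule serves as the
oracle in the test suite.

When a validation cohort is available, `runPipeline()` scores on its
tumor samples; otherwise it pools the discovery cohorts' tumor samples.
Pooling carries a caveat worth knowing: any cohort-level mean shift
(batch or platform effect) moves all affected genes together and inflates
cross-gene correlation in the pooled matrix. The synthetic generator
reproduces exactly this artifact through its per-cohort effect jitter,
which is why the package's own recovery checks score on the
single-cohort validation samples.

## qPCR validation

For each patient, `ΔCt = Ct(target) − Ct(reference)` within tissue,
`ΔΔCt = ΔCt(tumor) − ΔCt(adjacent)`, and fold change `2^−ΔΔCt`. Patients
with incomplete Ct blocks are excluded with a logged count; a missing
reference gene is a hard error. Testing is a paired two-sided Student's t
on per-patient ΔCt (equivalently a one-sample t on ΔΔCt): Ct-scale values
are closer to normal than fold changes, which are log-normal by
construction. An unpaired option exists. The all-differences-zero
degenerate case returns p = 1. The reference gene defaults to ACTB, the
standard β-actin housekeeping control (source material for this design
spelled it "ATCB", which we treat as a transposition of ACTB; the label is
configurable, so any housekeeping gene can be used).

# The synthetic-cohort generator

`simParams()` centralizes every knob; the defaults are the conditions the
screen is designed around, chosen once:

- **3 cohorts**, shared 1000-gene universe, **20 tumor + 20 normal
  samples each** — the scale of the public metastatic-PTC microarray
  cohorts this screen type consumes (tens of samples per cohort, a
  three-way intersection). 1000 genes keeps planted genes rare (2.3%)
  while every test stays fast.
- **8 upregulated + 15 downregulated planted genes** at effect
  Δ = 4 log2 units with per-cohort jitter sd 0.4 emulating
  inter-platform effect-size variability; per-gene Gaussian noise
  sd = 0.5 on the log2 scale, typical of processed microarray data.
  The planted set sizes mirror the funnel's expected shape (a handful of
  overexpressed genes, roughly twice as many lost differentiation genes).
- **4-gene core module** drawn from the downregulated set (thyroid
  differentiation programs are lost, not gained, in dedifferentiating
  tumors), sharing a single latent factor in tumor samples. The
  `loading` parameter (default 0.8) *is* the target pairwise Pearson r:
  the factor coefficient is `noiseSd · sqrt(loading / (1 − loading))`,
  giving within-module correlation ≈ loading and zero correlation
  elsewhere. One shared factor is the simplest mechanism producing the
  block-correlation structure the scoring stage consumes.
- **Survival**: n = 200 patients, exponential event times with log-hazard
  `log(0.02) + Σ coef · z_g` (baseline 0.02/month ≈ 35-month median at
  average expression, a plausible scale for cancer-cohort overall
  survival in months). Every planted gene carries |coef| = 1 per sd of
  expression, signed by its direction — the study premise that the whole
  risk set is prognostic. Censoring is uniform on (0, b), with b solved
  numerically (uniroot) so the *expected* censored fraction equals the
  configured rate (default 0.3) given the realized subject hazards;
  rate 0 disables censoring. Core-module genes keep their latent-factor
  correlation on the standardized scale, which gives them stronger
  marginal survival associations than isolated planted genes — so the
  OS filter passes the core module essentially always while thinning the
  rest, an emergent analog of published screens keeping 18 of 23 genes.
- **qPCR**: 8 paired patients (a realistic clinical validation set),
  planted ΔΔCt of ±2 cycles (|fold change| 4, sign matching direction:
  down-regulated genes gain cycles in tumor), measurement noise
  sd = 0.25 cycles, patient-level Ct offsets that cancel within ΔCt, and
  a zero-effect reference gene.

Everything is deterministic given `seed`; the survival, validation-cohort
and Ct generators use fixed offsets of the same seed so the pieces are
independent but jointly reproducible.

What the generator does **not** emulate: probe-level effects, RMA-style
normalization artifacts, batch structure within a cohort, platform
annotation mismatches (all cohorts share one gene universe),
non-exponential hazards, informative censoring, or qPCR amplification
efficiency differences. Passing recovery tests therefore demonstrate that
the pipeline's logic is correct under its own statistical model, not that
the screen is robust to real microarray pathology.

# Numerical and interface choices

- Strict gate inequalities everywhere (`> 2`, `< 0.05`); boundary values
  are not significant.
- Duplicate gene rows at import collapse to the max-mean row (the common
  microarray convention; `"mean"` is available); genes with missing
  values are dropped per cohort with a logged count.
- Expression tables round-trip bit-identically (written at 17 significant
  digits), and pipeline reports serialize to JSON at 17 significant
  digits so reloading is lossless.
- p-values are floored at the smallest positive double, never exactly 0.
- `readExpressionTable` skips `!`-prefixed lines, so series-matrix-style
  files load directly.
- The pipeline stops cleanly when an input is absent (`status =
  "partial"`, `completed_stages` records how far it got), mirroring a
  screen run before clinical data exist.

# Problem sizes in the test suite

The suite exercises the default study conditions directly: full
three-cohort pipeline runs at 1000 genes, 100-replicate scoring-recovery
and KM-agreement loops at 100 genes and n ≤ 50 respectively, a
1000-replicate log-rank null calibration at 50 + 50 subjects, and a
200-replicate qPCR null calibration. The complete suite runs in about
half a minute on one CPU; the acceptance script in about 20 seconds.

# Known limitations

- The Welch-on-raw-p DEG screen intentionally reproduces a web-tool-era
  analysis style; for new analyses a moderated test with FDR control is
  preferable, and this package's numbers will differ from such tools.
- Median dichotomization discards within-arm expression information; a
  Cox model on continuous expression would be more efficient but is out
  of scope.
- The correlation-bin score is a coarse, threshold-based centrality
  measure. It is faithful to the screening procedure it implements, but
  it is not a substitute for network inference, and ranks near bin
  boundaries are unstable at small n.
- The RFS pass reuses the same machinery on a second survival table; the
  package does not model competing risks or multi-state outcomes.
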