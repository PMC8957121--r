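# gbmseesaw

Tools for asking whether DNA methylation *changes* explain transcription
*changes* in invertebrate genomes — and for checking the class-level
"seesaw" hypothesis about the two methylation classes.

## The problem

Invertebrate DNA methylation is concentrated in gene bodies (gene body
methylation, GBM) and is bimodal: most genes are either essentially
unmethylated or methylated at tens of percent of their CpGs. Baseline GBM
correlates positively with transcription level and negatively with
transcriptional variability, which has motivated the idea that methylation
tunes expression. The sharper causal prediction — that between-condition
changes in GBM correlate with changes in transcription, per gene or as
reciprocal shifts of the two methylation classes (the seesaw: high class
moves one way in methylation, low class the other, transcription moving
opposite to methylation within each class) — is what this package tests.

`gbmseesaw` is for computational biologists with per-CpG bisulfite call
tables (Bismark-style cytosine reports), gene annotations (GFF3/BED), and
gene-level count matrices (RNA-seq, MBD-seq captured/unbound fractions,
mdRAD) for two conditions.

## What it computes

* **Quantification** — per gene and sample, percent methylation
  `100 * Σ meth / Σ (meth+unmeth)` over the CpGs in the gene body (or the
  1 kb strand-aware promoter window), with a coverage floor; log2 levels
  with a dataset-wide zero rule; MBD-scores
  (`mean log2(RPKM_captured / RPKM_unbound)`); RPKM; expression CV across
  control replicates; genomic-coverage estimates.
* **Classes** — hard 2.5% cutoff splitting genes into lowly and highly
  methylated classes.
* **Differential tests** — methylation: per-gene binomial GLM on
  (methylated, coverage) pairs with a condition effect, likelihood-ratio
  test (chi-square, 1 df), optional Pearson overdispersion correction;
  expression: median-of-ratios normalization, NB Wald test with
  method-of-moments dispersion referred to t(n1+n2−2); both with
  Benjamini–Hochberg FDR.
* **Hypothesis layer** — baseline correlations (GBM vs mean expression,
  |Δexpression|, CV), change–change correlations (ΔGBM or Δpromoter vs
  Δexpression, optionally FDR-restricted), and the three-component seesaw
  test with gene-resampling bootstrap CIs on class mean shifts.
* **Synthetic studies** — a fully parameterized generator
  (`simulateStudy()`) with planted classes, baseline structure, coupling,
  and seesaw shifts, plus a truth table, so every stage is validated by
  parameter recovery.

## Worked example

Simulate a default two-condition study (2,000 genes, bimodal GBM, no
planted methylation–expression coupling) and analyze it end to end:

```r
library(gbmseesaw)
study <- simulateStudy(simConfig(seed = 42))
res <- analyzeStudy(study, params = list(seed = 42))

res$baseline_correlations
#>    variable_x           variable_y    n           r  method subset
#>  log2_gbm_pct       mean_log2_rpkm 2000  0.78203650 pearson    all
#>  log2_gbm_pct abs_log2_fold_change 2000 -0.06681526 pearson    all
#>  log2_gbm_pct              cv_rpkm 2000 -0.46486376 pearson    all
```

Baseline structure behaves as in real data: GBM correlates positively
with mean expression (r = 0.78) and negatively with expression
variability (r = −0.46) and with the magnitude of between-condition
differences (r = −0.07).

```r
res$delta_correlations[, c("subset", "region", "n", "r")]
#>   subset    region    n            r
#>      all gene_body 2000  0.018357097
#>  de_only gene_body  548  0.011821581
#>  dm_only gene_body 1001  0.002284795
#>      all  promoter 1679 -0.046131022
```

With no planted coupling, the change–change correlations are null
(|r| < 0.05) for gene bodies and promoters, with or without FDR < 0.1
restriction — the per-gene "changes track changes" prediction finds
nothing here, as it should.

```r
res$seesaw
#> SeesawSummary (2000 bootstrap replicates)
#>   low  gbm    n=1076   mean -0.0324  [-0.0925, +0.0280]  null
#>   low  expr   n=1076   mean -0.0624  [-0.1313, +0.0064]  null
#>   high gbm    n=924    mean +0.0047  [-0.0223, +0.0308]  null
#>   high expr   n=924    mean +0.0057  [-0.0590, +0.0710]  null
#>   components:
#>     c1_reciprocal_gbm          not_supported
#>     c2_reciprocal_expression   not_supported
#>     c3_opposite_directions     not_supported
```

Each row is a class × variable mean shift with a bootstrap 95% CI; all
CIs span zero, so none of the three seesaw components is supported.
Re-simulating with `seesawDeltaGbmHigh = -0.4, seesawDeltaGbmLow = 0.4,
seesawDeltaExprHigh = 0.5, seesawDeltaExprLow = -0.5` flips all three
components to `supported`.

File-based studies run the same way through `runStudy("study.yaml")` or
the thin CLI (`exec/gbmseesaw simulate|run|quantify|seesaw`); every output
table carries `#` provenance headers, and identical configurations
reproduce byte-identical outputs.

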