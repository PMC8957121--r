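---
title: "Methods: gene body methylation, transcription, and class-level seesaw shifts"
author: "gbmseesaw maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene body methylation, transcription, and class-level seesaw shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbmseesaw)
```

# The scientific question

Invertebrate genomes methylate DNA almost exclusively inside gene bodies,
and gene body methylation (GBM) is bimodal: a lowly methylated class near
zero and a highly methylated class with tens of percent of CpGs methylated.
Baseline GBM correlates positively with transcription level and negatively
with transcriptional variability. Whether *changes* in GBM between
conditions drive *changes* in transcription is the open question this
package operationalizes. It quantifies both layers from standard sequencing
outputs, computes per-gene differential methylation and expression between
two conditions, and tests three families of hypotheses:

1. **Baseline relationships** — correlation of GBM level with mean
   expression, with the magnitude of between-condition expression
   differences, and with the coefficient of variation (CV) across control
   replicates.
2. **Change–change relationships** — correlation between per-gene
   differential methylation (gene body or 1 kb promoter window) and
   differential expression, optionally restricted to significant genes
   (FDR 0.1).
3. **The class-level "seesaw"** — whether the two methylation classes
   undergo (1) reciprocal mean shifts in GBM, (2) reciprocal mean shifts in
   transcription, and (3) opposite-direction shifts of transcription
   relative to GBM within each class.

# Quantification model

## Gene body and promoter methylation

For each gene and sample the package sums methylated and total read counts
over every CpG record within the gene bounds (both strands pooled, no
symmetric-CpG collapsing: counts are used as reported) and reports

\[ \mathrm{pct}_{gs} = 100 \cdot \frac{\sum_{c \in g} m_{cs}}{\sum_{c \in g} (m_{cs}+u_{cs})}. \]

Cells with summed coverage below `min_gene_cov` (default 10 reads; 0
disables) are missing rather than zero — a gene without informative
coverage is unmeasured, not unmethylated. The per-gene level is the mean of
per-sample percentages over non-missing samples (not a pooled-count ratio),
so deeply sequenced samples do not dominate. For plotting and correlation
on the log scale, zeros are replaced by the smallest non-zero value of the
dataset before `log2` (`log2WithZeroRule()`): the substitution is
dataset-wide so it is rank-preserving and affects only fully unmethylated
genes.

Promoter windows are the 1 kb immediately upstream of the annotated gene
5′ end, strand-aware and clipped to contig bounds; a window never overlaps
its own gene body, and overlapping another gene's body does not reduce its
counts — windows are independent intervals. We deliberately anchor on the
gene start rather than the first exon: the package has no exon model, and
for most invertebrate annotations the two coincide.

Two capture-based proxies are supported alongside: the MBD-score, the mean
over library pairs of log2(RPKM captured / RPKM unbound) with one read
added to every cell (finite, and antisymmetric under swapping fractions),
and mdRAD summarized as RPKM. RPKM is counts divided by gene length in kb
times library size in millions.

## Methylation classes

Genes are split at a hard cutoff of 2.5% mean methylation, the conventional
boundary between the two modes of the bimodal distribution. The tie at
exactly 2.5% goes to the high class, making the upper class closed and the
rule deterministic. No mixture model is fitted — the hard cutoff matches
how the field reports classes and keeps class membership reproducible.

# Differential tests

The differential layer is intentionally self-contained and fully specified,
so that every number it produces can be recomputed by hand or by an
independent oracle; its output schema (effect, p, BH q, tested flag)
mirrors the popular methylation and expression packages so externally
produced tables can be substituted.

## Differential methylation

Per gene, per-sample (methylated, coverage) pairs follow a binomial GLM
with a condition effect on the logit scale. With only an intercept and a
two-level factor the maximum-likelihood fit is closed-form — the fitted
probabilities are the condition-pooled proportions — and the test is the
likelihood-ratio statistic against the pooled model, referred to
chi-square with 1 df. Complete separation (a pooled 0% or 100%) is handled
by capping fitted logits at ±15 and flagging the gene. An optional Pearson
overdispersion correction divides the statistic by the null-model Pearson
dispersion when it exceeds 1, for data with extra-binomial variability
between replicates. Effects are reported as percentage-point differences
of pooled percents and as the log2 ratio of pooled percents after adding
0.5 reads to each pooled count (finite and antisymmetric); the log2 ratio
is the default axis for change–change correlations since the companion
expression effect is also a log2 ratio.

## Differential expression

Counts are normalized with median-of-ratios size factors (the median is
taken on the ratio scale; for odd gene counts this coincides exactly with
the common exp-median-log convention). The effect is the log2 ratio of
normalized condition means with a 0.5 pseudocount. A per-gene NB
dispersion is estimated by method of moments on normalized counts pooled
within conditions and floored at 1e-8, and the delta-method standard error
of the log2 ratio gives a Wald statistic. The statistic is referred to a
**t distribution with n1+n2−2 degrees of freedom**, not a normal: the
moment dispersion estimate carries only that many degrees of freedom, so
the statistic is t-like, and at six replicates per group a normal
reference inflates the 5% type-I error to roughly 9% while the t reference
holds it near nominal (the calibration test in the suite verifies
0.04–0.06 at 20,000 null genes). No dispersion shrinkage or independent
filtering is performed — those refinements matter for per-gene discovery
power, while the package's conclusions rest on correlations and class
means of effect sizes, which are robust to them.

BH false-discovery-rate adjustment is applied within each table
separately, matching per-study FDR reporting.

# The seesaw test

Classes come from `assignClasses()`; the shift variables are the
differential-GBM effect and the expression log2 fold change of all tested
genes (not only significant ones, mirroring how the class-level figures
use all points). For each class × variable the package reports the mean
shift with a gene-resampling percentile bootstrap 95% CI (default B =
2000, seeded; the bootstrap operationalizes what is otherwise a visual
density-shift judgment, which has no standard test). A verdict is
positive/negative when the CI excludes zero, null otherwise, and
inconclusive below a minimum class size of 20 genes — below that the CI
itself is unstable. Component 1 (reciprocal GBM) requires both class GBM
CIs to exclude zero with opposite signs; component 2 likewise for
expression; component 3 requires, within each class, non-null and opposite
GBM and expression verdicts. Verdicts, not CIs, are the contract: they are
invariant to gene order, and with a degenerate cutoff (0 or 100) the
single-class study returns inconclusive rather than fabricating a
reciprocal pattern.

Correlations default to Pearson on the log2 axes, since that is the scale
the relationships are usually drawn on; Spearman is available by argument
wherever a correlation is computed.

# The synthetic-study generator

`simulateStudy()` emits everything the pipeline reads — per-sample
cytosine reports, gene models, RNA-seq/MBD/mdRAD counts, a sample sheet —
plus the truth table that recovery tests compare against. It emulates:

* **bimodality**: each gene is high-class with probability 0.4; baseline
  methylation probabilities are Beta(mean 1%, concentration 50) in the low
  class and Beta(mean 60%, concentration 10) in the high class;
* **coverage**: ~20 CpGs per kb inside genes (10% of CpGs intergenic, so
  window logic is exercised against off-gene records), Poisson 30×
  coverage per CpG per sample, three samples per condition;
* **expression structure**: mean log2 RPKM increases with log2 GBM (slope
  0.3, gene-level sd 1), and NB dispersion is 0.2 in the low class versus
  0.05 in the high class, so transcriptional variability falls with
  methylation;
* **condition effects**: per-gene methylation shifts act on the logit
  scale (probabilities stay in (0,1)) and expression shifts on the log2
  scale; each is a class-level "seesaw" mean plus gene-level Gaussian
  noise, and a latent standard normal shared with loading sqrt(|rho|) by
  both sides makes the planted change–change correlation converge to
  `deltaCouplingRho`.

Free parameters the literature does not pin down were fixed once, at
design time. The methylation gene-noise sd is 0.5 logit units — one sd
moves a 60%-methylated gene by about 12 percentage points, already a
generous per-gene response for this kind of data. This choice matters: the
measured log2 percent ratio is a *compressed, noisy* image of the logit
shift (the logit→log-percent slope is ≈1 for nearly unmethylated genes but
1−p for methylated ones, and genes with near-zero methylation carry almost
no countable methylated reads at 30× coverage), so the pipeline-recovered
change–change correlation is attenuated by roughly 20–25% relative to the
planted value regardless of how the noise scales are set. Larger gene
noise would reduce that attenuation slightly but lets low-class genes with
large positive shifts cross the 2.5% cutoff into the measured high class,
cancelling planted class-level shifts; smaller noise does the reverse. The
default favors faithful seesaw recovery and honest nulls, and the
attenuation of the recovered correlation is documented rather than hidden.
The planted-seesaw magnitudes used in validation are −0.4/+0.4 logit for
the high/low classes (moving pooled high-class percents by ~10 points) and
+0.5/−0.5 log2 for expression, the sign pattern of the transplant
observation that motivated the seesaw hypothesis.

Randomness derives from one study seed through fixed per-component
sub-seeds (structure, CpG map, WGBS counts, expression, MBD, mdRAD), so
identical configurations reproduce byte-identical output files. R's RNG is
stream-based, so unlike a counter-based scheme, changing the gene count
does perturb all draws of a component.

**What the generator does not emulate** — and therefore what passing
recovery tests do not establish about real data: read-level artifacts
(mapping bias, bisulfite conversion error), batch effects between
replicates, genotype structure, exon architecture, and any nonlinear or
non-additive coupling between methylation and expression changes. Null
honesty and parameter recovery here validate the *statistics*, not the
biology.

# Numerical and operational choices

* Coordinates are 1-based inclusive everywhere internally; BED is
  converted on input. CpG context is accepted as "CpG" or "CG",
  case-insensitively.
* Pseudocounts: 1 read per cell for MBD RPKM, 0.5 reads per pooled count
  for the methylation log ratio, 0.5 normalized units for the expression
  log ratio — each the smallest symmetric choice keeping logs finite.
* Ties, caps, floors: class ties go high; logits cap at ±15 under
  separation; dispersions floor at 1e-8; BH q-values cap at 1.
* Degenerate inputs return missing values or inconclusive verdicts, never
  silent zeros: genes without covered CpGs, windows clipped away, classes
  below minimum size, zero-variance correlation axes.
* Configuration files are YAML (flat keys namespaced by concern); every
  output table opens with `#` provenance lines naming the package version
  and the resolved parameters, and a run log records contrast, parameters,
  and row counts per stage.
* Validation problem sizes were chosen for desk-scale runtimes: oracle
  equivalence on ~1,000 randomized small instances, calibration at 20,000
  null genes, null-honesty and coupling recovery at 10,000-gene studies
  across 20 seeds, structure recovery at the 2,000-gene default across 100
  seeds, with bootstrap B = 500–1,000 in the batched runs and B = 2000 as
  the user-facing default.

# Known limitations

* The differential stand-ins are deliberately simple: no dispersion
  shrinkage, no multi-factor designs, no per-CpG or tiled methylation
  tests, no covariates. Two-group contrasts only.
* Class assignment is a hard threshold; genes near 2.5% flip classes under
  measurement noise, which bounds truth-class recovery on synthetic data
  (~92% with the default generator, where ~11% of low-class baselines lie
  above the cutoff) and contaminates class means when per-gene methylation
  changes are large.
* Because classes are assigned on the all-sample mean, real per-gene
  methylation noise induces a regression-to-the-mean artifact: genes
  remaining in the low class are selected for downward shifts while
  upward-shifted genes cross into the high class, so even with no planted
  class effect the two classes can show small (|mean| ≈ 0.02–0.06 log2)
  opposite-sign shifts whose bootstrap CIs exclude zero at thousands of
  genes per class. In null simulations this flips the reciprocal-GBM
  component to "supported" in roughly one seed in ten. Apparent reciprocal
  class shifts of this magnitude should therefore not be read as seesaw
  evidence; assigning classes from control samples only removes the
  artifact but departs from the conventional all-sample basis.
* The recovered change–change correlation underestimates the planted
  coupling by the attenuation described above; comparisons of recovered
  correlations across datasets with different coverage are therefore not
  like-for-like.
* MBD and mdRAD are modeled phenomenologically (monotone mean functions,
  Poisson counts); their simulated scores validate plumbing and
  monotonicity, not capture chemistry.
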