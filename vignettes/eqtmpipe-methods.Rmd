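---
title: "Methods: integrative methylation-expression analysis with eqtmpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylation-expression analysis with eqtmpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`eqtmpipe` implements an integrative analysis for small clinical cohorts
profiled with whole-genome bisulphite sequencing (WGBS) and transcript-level
RNA-seq, stratified by a clinical severity score — the swollen joint count
over 66 joints (SJC66). The pipeline answers three questions in sequence:

1. **Which genes show transcript-level differential expression (GDE)?**
   Per-transcript p-values are combined to a gene-level p-value with the
   weighted Lancaster method, weighting each transcript by its base
   expression, followed by Benjamini–Hochberg adjustment across genes and a
   strict FDR < 0.05 call.
2. **Which of those genes also carry differential methylation?** Called
   differentially methylated regions (DMRs) are assigned to genes when they
   overlap a strand-aware window extending 5,000 bp upstream and 1,000 bp
   downstream of the gene body. Genes in the intersection are GDEMs (genes
   displaying both differential expression and methylation).
3. **How strongly is regional methylation coupled to expression (eQTM)?**
   For each GDEM × DMR × significant-transcript triple, the per-sample
   median percentage methylation over the DMR's constituent CpGs is
   correlated (Pearson) with log2-transformed normalized expression. The
   uncertainty of r comes from a 1,000-resample percentile bootstrap over
   samples; inference comes from a permutation null of 1,000 windows of
   consecutive CpGs of the same length drawn genome-wide.

### Stratification

Samples with SJC66 ≥ 9 form the high group, samples with 1–8 swollen
joints the low group; samples with SJC66 = 0 are excluded from all
comparative stages because clinically they mix very early disease with
treated disease in remission. The boundary is implemented as a strict
integer rule (8 is low, 9 is high). All differential tests share one
covariate design: intercept, sex (female = 0, male = 1), mean-centered age
in years, DMARD use (any disease-modifying anti-rheumatic drug, binary)
and the group indicator. Age is treated as continuous; centering only
stabilizes the intercept and leaves the group contrast untouched. A
covariate constant across retained samples is dropped with a warning
rather than producing a singular fit.

### The transcript-level test is a documented stand-in

The scientific content of the gene-level expression call is the
*aggregation*, not the per-transcript fit. The per-transcript test is
therefore a deliberately transparent ordinary-least-squares fit of
log2(normalized count + 1) on the covariate design, reporting the t
statistic and two-sided p of the group coefficient. It sits behind a small
interface (signed statistic, p-value, weight), so a negative-binomial GLM
can be substituted without touching the aggregation, intersection or eQTM
stages. Counts are normalized with median-of-ratios size factors computed
over transcripts with strictly positive counts in all samples.

Two degenerate cases are handled explicitly: transcripts with zero base
expression are dropped before testing, and transcripts with numerically
zero residual variance are flagged, with p floored (nonzero effect) or set
to 1 (zero effect) rather than producing 0/0.

### Weighted Lancaster aggregation

For p-values \(p_i\) with weights \(w_i\) (base expression), the statistic
is

\[ T = \sum_i G^{-1}\!\left(1 - p_i;\; \tfrac{w_i}{2},\, 2\right), \qquad
   p_{\text{gene}} = 1 - G\!\left(T;\; \tfrac{\sum_i w_i}{2},\, 2\right), \]

where \(G\) is the gamma CDF with the given shape and scale. With all
weights equal to 2 this reduces exactly to Fisher's method, which provides
an independent chi-square oracle used in the tests (agreement to
|Δp| < 1e−10 over 1,000 random cases). Tail probabilities are evaluated
with the gamma survival function directly (`lower.tail = FALSE`), which
remains accurate far into the tail without explicit log-space
bookkeeping. Transcripts with base expression below a configurable floor
(default 1 normalized count) are excluded: a near-zero weight contributes
a gamma component with shape ≈ 0 whose quantile transform is numerically
unstable and carries no information. Zero p-values are clamped to the
smallest positive double with a warning. Genes on configured allosomes
(sex chromosomes) are removed before testing to mitigate sex confounding,
which matters because the emulated cohort's sex distribution is
deliberately imbalanced between severity groups.

### DMR-to-gene annotation

"Within 5,000 bp upstream or 1,000 bp downstream of the gene" is
interpreted as overlap (≥ 1 bp) with the strand-aware extended gene body:
for a + strand gene the eligible window is
[gene_start − 5,000, gene_end + 1,000], mirrored for − strand genes.
Overlap rather than containment is used because reported DMRs can span
tens of kilobases, exceeding any plausible containment window. Both the
anchor (gene body vs TSS-only) and the overlap rule (any-overlap vs
DMR-midpoint-inside-window) are exposed as configuration, since annotation
tooling differs on these conventions. All qualifying genes are reported —
there is no nearest-gene collapsing — and a brute-force all-pairs oracle
with identical semantics backs the interval implementation in the tests.
BED input is 0-based half-open and converted to 1-based inclusive exactly
once at the read boundary.

### Concordance classification

Within a GDEM, only transcripts that are individually significant
(BH across all tested transcripts, q < 0.05) vote: a gene whose
significant transcripts carry both positive and negative effect signs is
classified `opposite`, otherwise `concordant`. Restricting the vote to
significant transcripts mirrors how transcript panels distinguish
significant from non-significant transcripts; an all-transcripts voting
mode is available. A gene with no significant transcript is reported
concordant with a flag rather than erroring, and exact duplicate
gene × DMR × transcript rows are de-duplicated with a logged count.

### eQTM: estimate, bootstrap, permutation

The per-sample regional methylation is the *median* percentage methylation
over covered constituent CpGs (coverage ≥ 1 read by default); a sample
with no covered CpG in the region is treated as missing and the pair is
dropped with a logged count. Expression enters as log2(normalized count +
1); the pseudocount is configurable.

The 95% CI is the percentile interval of r over 1,000 with-replacement
resamples of the n samples. Resamples in which either vector is constant
are discarded and redrawn — they carry no correlation information — and if
more than half of all draws are degenerate the data are deemed
pathological and an error is raised. Percentile bootstrap intervals
under-cover at n = 17; the acceptance suite therefore asserts ≥ 85%
empirical coverage for a true correlation of 0.8 rather than the nominal
95%.

The permutation null draws windows of L consecutive CpGs (L = the number
of CpGs in the observed DMR) uniformly over the autosomal CpG universe,
whole windows on one chromosome, excluding windows that overlap the
observed DMR. Each window's median-methylation vector is correlated with
the same expression vector. The default comparison is two-sided on |r|: a
literal "proportion of null correlations higher than observed" rule would
return p ≈ 1 for every strong negative correlation, which is inconsistent
with reporting small p-values for strongly negative eQTMs; the literal
one-sided rule remains available via `tail = "greater"`. A permutation p
of 0 is written as 0 in machine output with a companion display value
"< 1/N"; no pseudocount correction is applied. When fewer valid window
positions exist than requested, windows are drawn with replacement with a
warning. `perm_p × n_permutation` is always an integer; degenerate
windows (constant medians) are redrawn so this granularity is preserved.

## The synthetic-data generator

Because the analysis targets a 17-sample clinical design, every stage is
exercised on a generated miniature study with recorded planted truth. The
generator emulates:

* **Cohort**: 9 SJC66-high (scores 9–20) and 8 SJC66-low (1–8) samples by
  default, optional SJC66 = 0 samples, age uniform 25–70, DMARD use
  Bernoulli(0.5), and a deliberate sex confound (75% of high-group samples
  male, 75% of low-group female) so the covariate-adjustment paths are
  genuinely exercised.
* **Gene models**: genes of 1–50 kb on synthetic chromosomes
  (`chrS1`, `chrS2`, …, one per ~100 genes; synthetic names avoid
  collisions with real genomes), both strands, 1–5 transcripts sharing the
  TSS region.
* **Methylome**: each gene gets a promoter CpG cluster (~60 CpGs spanning
  TSS ± 1 kb, mostly unmethylated baseline), on top of 100,000 background
  CpGs with exponential spacing (mean 300 bp) and a bimodal beta-mixture
  baseline. Read counts are binomial given a Poisson(30) depth — the
  natural noise model for WGBS counts given depth. Planted DMRs shift a
  run of 10–50 consecutive CpGs near a target gene's promoter by ± 30
  percentage points in the high group (hypomethylation slightly more
  frequent, mirroring the usual excess of hypomethylated regions in
  inflamed tissue). The large background universe keeps the planted
  regions a ~1% minority of all CpGs, as in a real genome, so the
  permutation null is not contaminated by planted signal.
* **Counts**: negative-binomial (dispersion 0.05) around gene-level
  baselines with per-sample library-size factors. Planted differentially
  expressed transcripts receive |log2FC| = 2; discordant genes get
  transcripts of both signs. For each planted GDEM, one designated
  transcript's latent log2 mean is coupled to the sample's realized median
  planted-DMR methylation through a Gaussian-copula-style link
  \(z = \rho z_m + \sqrt{1 - \rho^2}\,\varepsilon\), scaled by a log2-SD
  of 1.5, with sign opposite to promoter methylation (the default
  repressive direction). This makes the target correlation magnitude
  \(\rho\) (default 0.9) directly interpretable: the realized Pearson r is
  \(\rho\) attenuated slightly by counting noise. The coupling scale was
  chosen so the implied group fold change is comparable to the planted
  |log2FC|.

What the generator does **not** emulate: read-level data and bisulphite
conversion, realistic human gene structure, spatial autocorrelation of
methylation beyond the planted runs, cell-type mixture effects, and
outlier samples. Passing tests therefore demonstrate the correctness and
calibration of the computations under a clean generative model, not
robustness to every pathology of real tissue data.

## Numerical and design choices

* **Determinism.** One global seed fans out to per-stage (and per-pair)
  child seeds via a deterministic hash of the stage name, so any stage can
  be re-run in isolation and full reruns are byte-identical. Output tables
  carry a provenance line (package version, seed, configuration hash —
  deliberately no timestamp). The output directory is excluded from the
  configuration hash because it does not influence any computed value.
* **Thresholds.** Every threshold surfacing in results (FDR 0.05, window
  5,000/1,000 bp, 1,000 bootstraps/permutations, SJC66 cutoffs) lives in a
  configuration object; stage code never hard-codes them.
* **FDR procedure.** "FDR-adjusted" is implemented as Benjamini–Hochberg;
  the procedure is pluggable.
* **Lancaster weights** are the raw base-expression means (no rescaling);
  rescaling all weights by a constant does change the Lancaster p in
  general, so this choice is exposed to the caller via the weight vector.
* **Problem sizes.** The bundled checks run the default study (17 samples,
  100 genes, ~112,000 CpGs, 20 planted GDEMs), a 200-gene null study for
  permutation calibration, 500 replicates for bootstrap coverage and 20
  seeds for eQTM power — sizes at which each check completes in minutes on
  one core while leaving Monte-Carlo noise well inside the asserted
  margins.

## Known limitations

* The per-transcript OLS stand-in is less powerful than a tuned
  negative-binomial fit at very low counts; conclusions about *aggregation*
  behavior are unaffected, which is why the interface keeps the test
  pluggable.
* Permutation p-values have granularity 1/N (default 1/1,000); reported
  zeros mean "below 1/N", not literal impossibility.
* The eQTM correlation is unadjusted for covariates by design; with a
  sex-confounded severity contrast, part of an observed methylation–
  expression correlation can be group-driven. The permutation null
  (windows sharing the same sample structure) accounts for this at the
  level of inference, but the point estimate remains a marginal
  correlation.
* With 17 samples, a single influential sample can move r substantially;
  the bootstrap CI, not the point estimate, is the honest summary.
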