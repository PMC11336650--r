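---
title: "Polytranscriptomic scoring and TWAS-based gene prioritisation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polytranscriptomic scoring and TWAS-based gene prioritisation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptscore)
```

## The problem

Transcriptome- and proteome-wide association studies (TWAS/PWAS) regress a
GWAS phenotype on genetically predicted expression or protein levels and
return a signed gene-level Z-score: positive Z means genetically higher
expression accompanies higher disease risk. `ptscore` implements the
downstream analyses that consume such summary statistics for a
case-control disease such as amyotrophic lateral sclerosis (ALS):

1. **triage** of high-confidence disease genes by combining association
   significance with colocalisation and fine-mapping evidence;
2. **polytranscriptomic scores (PTS)** — per-individual risk scores built
   from *observed* expression weighted by TWAS Z-scores — and their
   evaluation against disease status and clinical outcomes on the
   liability scale, meta-analysed across expression platforms;
3. **directional drug and ATC drug-class enrichment** from a
   DrugTargetor-style drug-gene interaction table;
4. **concordance** of TWAS-inferred versus observed case-control
   differential expression.

Because the real inputs (GWAS summary statistics, reference eQTL panels,
GEO expression series) are large external resources, the package ships a
first-class synthetic-data module that generates every input with known
ground truth, making all stages testable end to end.

## Gene triage

A gene is called high-confidence if it satisfies at least one of:

* **finemap** — a fine-mapping 95 % credible set lies entirely within the
  gene body (window configurable, default 0 bp: the gene body only, since
  no specific window convention is established for containment);
* **fusion_coloc** — a FUSION-style record is FDR-significant and
  `PP4/(PP3 + PP4) > 0.8`, i.e. the shared-causal-variant model dominates
  the linkage model (the no-association models are ignored because the
  TWAS has already established association);
* **smr_heidi** — an SMR-style record is FDR-significant and the HEIDI
  heterogeneity p-value exceeds 0.05.

Both boundary rules are strict inequalities. FDR correction
(Benjamini–Hochberg, via `stats::p.adjust`) is applied within each method
across all its panels jointly; expression and protein records are pooled
within a method by default, with `pool_molecules = FALSE` exposing the
separate-stream alternative, since conventions differ between studies.
Gene-level MAGMA-style associations are deliberately *not* a
high-confidence criterion: they are liable to LD confounding and carry no
colocalisation evidence.

## Polytranscriptomic scores

With standardized observed expression $z_{ig}$ (gene $g$, individual $i$)
and per-gene weights $w_g$, the score is

$$\mathrm{PTS}_i = \sum_{g} w_g \, z_{ig}.$$

Weights are averaged TWAS Z-scores after clumping and thresholding,
mirroring the clumping-and-thresholding construction of polygenic scores:

* features are gene × panel predicted-expression tracks; pairwise Pearson
  correlations are computed within a 500 kb window (gap between the
  closest gene-interval edges; overlapping genes have gap 0);
* **clumping** is greedy: sort by p-value (ties broken lexicographically
  by feature id for determinism), keep the best remaining feature as a
  lead, remove all features with $r^2 > 0.1$ against it, repeat.
  Correlations absent from the windowed matrix are treated as zero —
  features beyond the window are uncorrelated by construction;
* features are pooled across panels in one clumping pass (cross-panel
  same-gene correlation is part of the matrix), and Z-averaging happens
  strictly after clumping;
* a grid of p-value inclusion thresholds
  (`r paste(format(default_threshold_grid()), collapse = ", ")`) is
  applied; weight sets are further stratified by tissue (all / blood /
  brain) and optionally restricted to colocalised associations
  (`PP4 > 0.8` — the PP4/PP3 ratio is deliberately not used here, as it
  is unstable for genes included at lenient thresholds).

Expression is standardized gene-wise to mean 0 and unit *sample*
standard deviation (n − 1), computed across the whole cohort, cases and
controls pooled — the standard convention in risk-score work and the
scale on which the simulator's liability model is defined. Weight-set
genes unmeasured on a platform are skipped without imputation, and the
realized overlap is reported (`n_genes_used`); array platforms genuinely
differ in gene coverage.

## Association evaluation on the liability scale

Each PTS is tested by ordinary least squares with sex as covariate, for
case-control status (all samples) and, within cases only, spinal-vs-bulbar
site of onset, age at onset and survival. Survival is analysed by linear
regression, not proportional hazards, matching the upstream design. The
reported effect is the PTS coefficient; the variance explained is the
incremental $R^2$ of the full model over the sex-only model, the
convention of the polygenic-score literature.

For binary outcomes the observed-scale $R^2$ is converted to the
liability scale with the ascertainment-corrected transformation of Lee et
al. (2012, *Genet Epidemiol* 36:214–224): with prevalence $K$, sample case
proportion $P$, $t = \Phi^{-1}(1-K)$, $z = \phi(t)$, $m = z/K$,

$$C = \frac{K^2(1-K)^2}{z^2 P(1-P)}, \qquad
\theta = \frac{m(P-K)}{1-K}\Big(\frac{m(P-K)}{1-K} - t\Big), \qquad
R^2_l = \frac{C\,R^2_o}{1 + C\,\theta\,R^2_o}.$$

$K = 1/300$ is the default disease prevalence; onset site uses the
convention $K = 0.5$ to ease comparison across studies. $P$ is always
taken from the data at hand.

Platforms are combined by inverse-variance weighting of the PTS
coefficients; the meta-level $R^2$ is reconstructed from the meta Z and
pooled residual degrees of freedom as $t^2/(t^2+\mathrm{df})$, a
documented approximation. Best-threshold reporting takes the maximum over
the grid with no out-of-sample correction; this optimism is flagged in
the output header and is the reason the fully null calibration check
bounds the *maximum*, not a single threshold.

## Drug and ATC enrichment

Interaction labels are coded −1 (`DECREASED_EXPRESSION`,
`NEGATIVE_RESPONSE`, `OPPOSITE_RESPONSE`), +1 (`INCREASED_EXPRESSION`,
`POSITIVE_RESPONSE`) or 0 (`UNDIRECTED`); the vocabulary is closed and
unknown labels are rejected. Drugs need at least two genes with available
statistics to be tested.

The built-in signed statistic is a standardized concordance: over a
drug's directional interactions, $S = \sum_g c_g Z_g$, standardized under
the permutation null that reassigns the drug's codes to genes drawn
without replacement from the measured universe, with closed-form moments
$E[S] = \mu_Z \sum c_g$ and
$\mathrm{Var}[S] = \sigma^2_Z\,(N\sum c_g^2 - (\sum c_g)^2)/(N-1)$.
The reported z is the *negated* standardized S, so positive z = the drug
pushes expression against the risk direction (predicted protective),
matching the usual presentation of directional drug enrichment. External
directional engines (TWAS-GSEA-like mixed models) are out of scope;
drug-level statistics from such tools can be supplied directly, in which
case only the ATC-level analysis runs.

p-values come from the permutation null itself: exact enumeration when a
drug has ≤ 8 directional genes *and* the enumeration is feasible (the
assignment count is bounded, which a 1 000-gene universe exceeds already
at 3 genes), otherwise vectorized Monte Carlo resampling (B = 4999,
estimator (1 + hits)/(B + 1)). A normal tail was rejected here on
calibration grounds: after clumping, the gene universe consists of
block-lead Z-scores, a short-tailed (platykurtic) distribution for which
the normal approximation to a 3–8-term sum is visibly miscalibrated,
while the resampled p-values are uniform under the null.

The unsigned analogue ranks a drug's member genes' χ²-scale statistics
against non-members by a one-sided Wilcoxon rank-sum test.

ATC level-3 classes with ≥ 5 tested drugs are compared against all other
tested drugs by Wilcoxon rank-sum on the drug-level z — two-sided for the
signed statistic (direction summarized by the class median z), one-sided
for unsigned ones. Ties (which legitimately arise when two drugs share
identical measured interactions) switch the test to midranks with the
normal approximation and continuity correction; small untied samples use
the exact distribution. A drug mapped to several classes contributes to
each by default (`multiple = "first"` restricts to the first code). BH
correction is applied across classes.

## Observed differential expression and concordance

Probe-level matrices are averaged across probes per gene
(`limma::avereps`) and then log2-transformed. Per-gene differential
expression is the Pearson (point-biserial) correlation between 0/1 case
status and expression, with the t-transform p-value and BH correction; no
sex adjustment is applied (plain correlation is the convention for this
comparison, and the discrepancy with the sex-adjusted PTS models is
intentional and documented). Platforms are meta-analysed on Fisher's z
scale with variance $1/(n-3)$ — the variance-stabilized standard for
correlations; inverse-variance weighting of raw r is available via
`meta_diffexpr(scale = "raw")`. A gene is **concordant** when its
observed correlation is FDR-significant with the same sign as its TWAS
direction (mean Z across panels), **discordant** on the opposite sign,
and unclassifiable when the mean Z is numerically zero rather than being
forced to a side.

## The synthetic study

`sim_config()` fixes the study conditions; the defaults are the
conditions the package's calibration and recovery tests run under:

* **genes**: 1 000 genes in blocks of 10 laid on chromosomes 1–22 so each
  block spans < 500 kb and consecutive blocks are > 500 kb apart;
  compound-symmetry correlation 0.6 within blocks (r² = 0.36, above the
  0.1 clumping threshold, so clumping genuinely collapses blocks) and
  0.9 between panels for the same gene (kept below 1 so correlation
  blocks stay positive definite; the feature correlation is a Kronecker
  product of two compound-symmetry matrices and therefore positive
  semi-definite by construction);
* **TWAS**: four expression panels (two blood, two brain), a FUSION-style
  and an SMR-style record each; 50 signal genes in distinct blocks with
  |Z| ~ N(6, 1) and sign agreement 1 across panels; null Z standard
  normal; p is the exact two-sided normal tail of Z. PP4 is Beta(20, 2)
  for signal and Beta(1.5, 10) for null genes with PP3 a uniform fraction
  of the remainder. HEIDI p is uniform for signal genes; 80 % of null
  genes draw Beta(1, 50): spurious associations are predominantly
  linkage-driven, which is precisely the failure mode HEIDI detects, and
  in practice most marginally significant SMR hits fail HEIDI;
* **cohorts**: a liability-threshold disease model. The true score
  $s_i = \sum_g w_g z_{ig}$ over the signal genes (weights = true Z) is
  scaled by $c$ so that $c^2\mathrm{Var}(s)$ equals the target liability
  variance (default 0.05, the scale of a strong transcriptomic
  predictor); liability $L = c\,s + e$ with standard-normal residual,
  disease iff $L > \Phi^{-1}(1-K)$, $K = 1/300$ (a lifetime-risk-scale
  prevalence). Case-control ascertainment (2 000 + 2 000 per platform,
  two platforms) is performed by *conditional* sampling — liability from
  the truncated normal, score given liability, expression given score,
  block by block — which is exact, leaves the phenotype model untouched,
  and avoids 1/K-sized rejection pools; the tests verify it against
  brute-force rejection sampling at a tractable prevalence. Within
  cases, onset site (liability model, spinal prevalence 0.65, effect
  0.25 per SD of true score), age at onset (56 ± 10 years, +2 years per
  SD) and survival (36 ± 18 months, −6 months per SD, uncensored —
  survival is analysed by linear regression, so censoring is out of
  model) depend linearly on the standardized true score. Platforms get a
  small global shift (±0.1) and 10 % per-gene dropout, disjoint across
  platforms, to exercise missing-gene handling;
* **drugs**: 200 drugs with 2 + Poisson(23) gene interactions each —
  deliberately broad polypharmacology, both realistic for curated
  drug-gene databases and necessary for null drugs to retain ≥ 2 genes
  inside the clump-restricted statistic universe (~1 gene per block);
  8 planted protective drugs each target 6 signal genes with direction
  opposing the gene's risk sign and share one ATC class; 15 % of
  interactions are undirected.

What the generator does **not** emulate: batch and cell-composition
effects, probe-level noise, censored survival, case oversampling bias in
expression normalization beyond what standardization induces, and —
importantly — *reverse causation*: observed differential expression in
the simulation is always a consequence of the liability-causing
expression itself, so discordant TWAS-vs-observed genes essentially never
arise under the defaults. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated generative model, not
robustness to the confounding structure of real post-diagnosis expression
data.

## Numerical choices

* Determinism: every generator seeds its own stream from the master seed
  with fixed offsets, so adding a stage never perturbs earlier draws;
  identical configurations reproduce identical bytes.
* Conditional covariance factors are computed by symmetric
  eigendecomposition with negative eigenvalues clipped at zero (they are
  −1e−16-scale rank artefacts).
* Zero-variance genes/features are dropped with warnings, never silently
  imputed; degenerate regressions (constant outcome or score) raise
  errors naming the offending column.
* `clump` ties on p are broken lexicographically by feature id.
* The BH step is `stats::p.adjust(method = "BH")`, verified in the test
  suite against an independent implementation of the step-up definition.

## Problem sizes in the test suite

The acceptance-style tests run the defaults above over 20 seeds for the
null-calibration, signal-recovery, triage-recovery and drug-class
recovery properties, and use 1 000 random instances (≤ 10 features) for
the clumping oracle; these sizes give Monte-Carlo error comfortably
inside the asserted bounds while keeping the default test run fast.

## Limitations

* The liability-scale conversion assumes the standard Lee et al. model;
  other conversions (e.g. probit regression on the liability directly)
  are not implemented.
* Best-threshold selection is in-sample and optimistic by design,
  mirroring common practice; no cross-validation machinery is provided.
* The signed drug statistic is a purpose-built stand-in with exact and
  resampled permutation inference; it is not a reimplementation of any
  published mixed-model enrichment engine, and external drug-level
  statistics can be substituted where those are available.
* No genotype-level simulation: fine-mapping enters only as credible-set
  position lists, and predicted-expression correlation is simulated
  directly rather than derived from SNP weights.
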