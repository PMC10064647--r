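---
title: "Methods: methylome-transcriptome integration for an epigenetic repression signature"
author: "mgstress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-transcriptome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgstress)
```

This vignette is the package's own account of the models and procedural
choices behind each stage, the parameters that matter, what the synthetic
data generator emulates (and does not), and the numerical decisions taken
where the procedure left room.

## The problem

Methylglyoxal (MG) is a reactive dicarbonyl detoxified by glyoxalase 1
(GLO1). When GLO1 is depleted in breast cancer cells, chronic MG stress
drives genome-wide DNA hypermethylation that preferentially silences
tumor-suppressor programs. The analysis chain implemented here turns that
biology into a sequence of concrete computations: call differentially
methylated CpGs between control and GLO1-depleted arrays, call
differentially expressed genes, find the gene-set programs that are both
hypermethylated and underexpressed, intersect everything into a compact gene
signature of the stress, score patients by it, and ask whether the score
stratifies survival.

## Methylation model

**β and M scales.** β = M/(U+M) is the methylated fraction at a CpG, in
[0, 1]; the formula uses no intensity offset (an offset is available via
`compute_beta(offset =)` for users who want the stabilized variant, default
0). Statistical testing happens on M-values, log2(β/(1−β)), which
approximately stabilize the variance; β is clipped to [1e−6, 1−1e−6] before
the log-ratio so boundary values stay finite. The round trip β → M → β is
exact to 1e−9 away from the boundary.

**Filtering.** A probe is dropped if it fails detection (p > 0.05) in *any*
sample — the conservative reading of a per-sample detection matrix — or is
cross-reactive, SNP-overlapping, or on chrX/chrY. Every removal is logged
with its reason.

**Peak-based type II correction.** The two Infinium chemistries report
different dynamic ranges: type II probes compress extreme β toward 0.5. Per
sample, the M-value densities of type I and type II probes are estimated by
Gaussian KDE with Silverman's bandwidth (`stats::density`, `bw = "nrd0"`);
the highest local maximum on each side of M = 0 gives the unmethylated and
methylated peaks of each design; type II M-values are rescaled linearly on
each side of zero so their peaks land on the type I peaks, and transformed
back to β. Type I values are never touched. The correction is a per-side
linear map, so it preserves the within-sample rank order of type II probes
on each side of β = 0.5. Degenerate inputs pass through with a warning: fewer
than 50 probes of either design, or a sample whose density has no local
maximum on one side of zero.

**Differential methylation.** Δβ is the difference of per-condition medians
of β (case − control; medians, not means, following the robust convention at
3 vs 6 replicates). Significance is a Welch t-test on M-values — the
variance of M genuinely differs between a group sitting at β ≈ 0.1 and one
shifted to β ≈ 0.4, so the unequal-variance form is the defensible default —
with Benjamini–Hochberg correction across all retained probes in one pass
(not per chromosome or region). A CpG is called hyper when Δβ > 0.2 *and*
adjusted p < 0.05, hypo when Δβ < −0.2; both inequalities are strict, so
Δβ = 0.2 exactly is not a call. Probes with zero variance in both groups
get p = 1 and are logged rather than dropped.

## Differential expression

The integration consumes a table with two FDR-corrected tests per gene
(likelihood-ratio and Wald) and the Wald β as fold-change proxy; a gene is
differential only when it passes *both* tests at FDR < 0.05, and direction
comes from the sign of β. `load_deg_table()` always recomputes the status
from the numbers and ignores any status column in the file.

`standin_de()` provides the in-package substitute: a pooled-variance t-test
on log2(TPM+1), with the single BH-corrected q filling both q slots so the
two-test AND-rule is preserved structurally and a real two-test table drops
in unchanged. Pooled rather than Welch variance is deliberate here: both
arms share one noise model in this stand-in's scope, and at 3 vs 6
replicates the pooled test keeps 7 degrees of freedom where Welch collapses
to ~2–4 and loses the planted 2-fold repression. The pseudo-count of 1 in
log2(TPM+1) is the standard choice. Genes whose *control-arm* mean TPM is
below 1 are flagged `low_expressed`; all-zero genes are retained with p = 1.

## Preranked GSEA

Gene-level methylation scores aggregate CpG-level Δβ by the max-|Δβ| CpG
among a gene's promoter, enhancer and mixed assignments, keeping its sign:
the most-affected regulatory CpG is taken to drive silencing (a `mean` rule
is available via the aggregation option). Ranking is descending with
lexicographic tie-breaks for reproducibility.

The enrichment score is the classic weighted Kolmogorov–Smirnov running sum:
increments |score|^p / Σ|score|^p at set members, decrements 1/(N−Nh)
elsewhere; ES is the extremum. `weight_p` defaults to 1 (the "weighted"
convention); 0 recovers the unweighted KS statistic. Near-ties between the
positive and negative extreme (within 1e−9, which occurs for rational
unweighted walks) resolve to the earliest position. A set covering the whole
list is degenerate (ES = 1, flagged).

Significance uses gene-tag permutation — the only null available to a
preranked analysis: `n_perm` (default 1000) random member sets of the same
size. NES divides ES by the mean of same-sign null ES; the nominal p is
one-sided within the same-sign pool with a 1/(n_perm+1) floor when the pool
is empty; the FDR q compares each NES against the pooled normalized null NES
of its sign relative to the observed NES of that sign (the
positive/negative-pool procedure). A set is significant when both
p < 0.05 and q < 0.05; "epigenetically repressed pathways" are those
significant with positive NES on the methylation ranking *and* negative NES
on the expression ranking.

## Integration and the signature

A gene is regulatory-hypermethylated if ≥ 1 hyper CpG sits in its promoter,
enhancer or mixed assignment; mixed regions (probes that are promoter in
some cell types and enhancer in others) count as regulatory. Gene-body
methylation is tracked separately and never feeds the regulatory flags.
Genes both hyper- and hypomethylated in regulatory regions are conflicting
and excluded from the two inverse-relation lists (they remain in the
output's `conflicted` slot).

The signature is the *collective* gene content of the repressed pathways
(union of members) intersected with the repressed-gene list. "The genes
composing these pathways" is read as the union because a strict per-pathway
intersection of several ~100-gene sets is near-empty by construction; the
strict intersection remains available via `derive_signature(mode =
"intersection")`.

## Scoring and refinement

The signature score z-scores each signature gene across patients, averages
per patient, and negates, so a high score means the signature genes are
*low* — strong repression, high stress. The z-score uses the sample standard
deviation (n−1), matching R's `scale()` on which the published scoring
function rests; population SD is available via `sd_type`. Zero-variance
genes are excluded from the per-patient mean and counted. The score is
mean-zero across patients, invariant to positive affine rescaling of any
gene, equivariant under patient permutation, and anti-monotone in any single
signature-gene expression value.

Refinement correlates each candidate gene's expression (Pearson) with its
pathway's *module expression profile* — the mean z-scored expression of the
pathway's members, i.e. the negated module score — and keeps the gene when
R > 0.25 and p < 0.05 (strict) for at least one of its pathways. The
correlation is taken against the expression profile rather than the negated
score deliberately: a repressed gene tracking its co-repressed pathway then
correlates *positively*, which is both the selection the optimization
heatmap convention displays and the only reading under which genes loaded on
the latent stress factor can pass a positive-R filter. The per-gene p is
raw (uncorrected), noted in the output; genes in several pathways qualify
through any one of them; constant genes are dropped with a message.

## Survival

Patients are sorted by score (ties broken by patient id, deterministically)
and cut into tertiles with the remainder going to the outer groups: low and
high both get ceiling(n/3), which reproduces the 93/91/93 split of a
277-patient cohort and compares 93 low vs 93 high. A median scheme is also
available. Kaplan–Meier estimation and the two-group log-rank test
(hypergeometric variance, no continuity correction, χ² with 1 df) are
delegated to the `survival` package behind the module's interface and are
checked in the tests against hand-computed product-limit tables and an
independent observed/expected tabulation. The module is endpoint-agnostic:
disease-specific or overall survival are both just (time, event) pairs. With
no events anywhere the log-rank is undefined and reported as p = 1 with a
warning. Score-vs-score panels use Spearman correlation by default, the
convention for signature-score comparisons.

## The synthetic-data generator

The generator's defaults are the study conditions the pipeline targets:

* **Design**: 3 control vs 6 case arrays; 10,000 probes over 2,000 genes.
* **Baseline β**: an equal-weight two-component Beta mixture with modes at
  0.10 and 0.90 (component concentration 30), reproducing the bimodal
  marginal of Infinium arrays.
* **Replicate noise**: Beta-distributed around each probe's target with
  concentration 1000, i.e. a replicate SD of ~0.010–0.016 — the
  reproducibility range of Infinium arrays. This is what makes a Δβ = 0.3
  shift detectable at all at 3 vs 6 with a Welch test, whose effective df is
  ~2 when the three-replicate arm dominates the variance.
* **Plants**: 8% of probes hyper (+0.30 β in cases), 1.2% hypo (−0.30),
  giving the ~87/13 hyper/hypo DMC split characteristic of the MG-stress
  response. Each of the 100 repressed genes is anchored by one planted
  hyper probe in its promoter/enhancer; the remaining regulatory hyper
  plants are rewired to repressed genes with probability 0.7, producing
  DMR-like clusters — hypermethylation concentrated on the silenced genes
  rather than scattered uniformly.
* **Probe chemistry**: 70% type II, compressed by β' = 0.5 + 0.8(β − 0.5),
  a one-parameter distortion sufficient to exercise the peak correction.
  Intensities are log-normal around 5,000 counts with 3% multiplicative
  channel noise; the β computation is scale-invariant, so the intensity
  scale is cosmetic.
* **Expression**: log-normal baselines (median ~20 TPM; repressed genes
  ~60 TPM so their repression is transcriptional, not detection-limited),
  log2-scale replicate SD 0.10, planted log2 fold change −1 on repressed
  genes in cases.
* **Gene sets**: 30 sets of 80–150 genes — the size range of curated
  oncogenic-signature collections (the six pathways of the motivating
  analysis hold 872 genes). Three causal TSG-A sets draw 60% of their
  members from the repressed genes; decoys are uniform. Small sets
  (tens of genes) were found to make the weighted ES saturate and the
  causal/decoy distinction unstable, which is an intrinsic property of the
  weighted statistic on near-degenerate score distributions, not a bug.
* **Cohort**: 200 patients; a latent standard-normal stress score; signature
  genes load −0.6 on it (high stress, low expression) over unit noise;
  exponential survival with log-hazard 0.8 per score unit and a baseline
  event rate of 1/60 months; independent exponential censoring tuned to a
  30% censored fraction.
* **Determinism**: one master seed fans out to fixed per-generator
  sub-streams, so each dataset can be regenerated independently and
  byte-identically.

What the generator does *not* emulate — and what green tests therefore do
not certify on real data: IDAT decoding, dye/batch effects, cell-composition
heterogeneity, correlated CpG blocks beyond the planted gene-level clusters,
read-level RNA-seq variability (counts are drawn at gene level),
copy-number/SNP artifacts, and real cohorts' non-exponential hazards and
informative censoring.

## Problem sizes used in validation

The test-suite and acceptance computations run at the defaults above
(10,000 probes, 2,000 genes, 200 patients, 1,000 GSEA permutations), with
the log-rank level/power simulation at 300 patients × 200 replicates and
module tests on reduced configurations (~2,000 probes) where the property
under test does not depend on scale.

## Known limitations

* The exact published gene identities and cohort statistics (the 60- and
  14-gene lists, cohort correlations, the p = 0.015 METABRIC split) depend
  on the deposited arrays and consortium cohorts and are outside what a
  synthetic run can or should reproduce; the pipeline reproduces the
  *procedure* and its printed arithmetic.
* The peak correction assumes a bimodal per-sample M distribution per
  design; strongly degenerate samples pass through uncorrected (with a
  warning) rather than being force-fitted.
* Gene-tag permutation understates inter-gene correlation relative to
  phenotype permutation; it is the only option for a preranked analysis and
  is used with that caveat.
* The refinement p-values are not multiplicity-corrected (the kept set is
  determined jointly by the R and p thresholds; at cohort scale the R
  threshold dominates).
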