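---
title: "Repeat-aware cell-free RNA profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat-aware cell-free RNA profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfrepeat)
```

## The problem

Standard RNA-seq references annotate genes but not the millions of
individual repeat-element insertions (SINE, LINE, LTR retroelements,
simple repeats) that make up roughly half of the human genome. In
cell-free RNA from blood plasma, repeat-derived transcripts are abundant
and disease-associated, but with a gene-only ("repeat-naive") reference
the reads they produce are simply lost. Treating every repeat instance as
an independent feature is equally unworkable: ~5 million features, most
of them near-identical copies that no aligner can distinguish.

`cfrepeat` takes the middle road. Each repeat instance is modelled as a
"transcript" of its subfamily "gene" (e.g. every AluY copy is a
transcript of the feature `rmsk:AluY`), exactly as transcripts aggregate
to genes in alignment-free quantification. This collapses millions of
instances to roughly 10^4 subfamily features — few enough for statistics
and classification, while still capturing which repeat families are
transcribed.

## The feature catalog

`build_catalog()` unifies two annotation sources into one namespace:

* genes from a GENCODE-dialect GTF (grouped by `gene_type` biotype), and
* repeat instances from a UCSC RepeatMasker-dialect table (grouped by
  `repClass` superfamily after stripping the uncertainty suffix
  `"SINE?" -> "SINE"`).

Repeat features are prefixed `rmsk:` so a pathological gene named like a
subfamily can never collide. Three catalog modes — `repeat_naive`
(genes), `repeat_alone` (subfamilies) and `repeat_aware` (their disjoint
union) — let every downstream analysis be run in matched naive/aware
pairs. Coordinates are held 0-based half-open internally; the rmsk table
is already in that convention and GTF records are converted on parse.
Simple-repeat names such as `(TA)n` are valid subfamily identities, and
no minimum instance length is imposed. Overlapping gene and repeat loci
are indexed as independent reference units; the quantifier, not the
catalog, is responsible for distributing multi-mapping reads.

## Quantification and aggregation

`aggregate_counts()` sums estimated reads (`NumReads` in the quant.sf
dialect) over all units mapping to a feature. Estimated counts, not TPM,
feed differential expression, mirroring the default behaviour of
transcript-import workflows. Fractional counts from probabilistic
assignment are preserved through aggregation and only rounded where the
negative-binomial likelihood requires integers. Units missing from the
catalog are dropped with a warning rather than failing, tolerating
catalog/reference drift; the mass balance (matrix total = resolvable
read total) is asserted in tests to 1e-9.

The per-sample mapping rate (assigned / sequenced reads) compared between
matched naive and aware references quantifies what repeat awareness
recovers; the comparison uses the paired two-sided Wilcoxon signed-rank
test.

## Normalization, entropy and other feature engineering

Between-library normalization is median-of-ratios: features positive in
all samples define a geometric-mean pseudo-reference, and each sample's
size factor is the median ratio to it. The implementation is checked in
the test suite against an independent reference implementation.

Two composition statistics summarise each sample:

* **fractions** — share of normalized counts per group (biotype or repeat
  superfamily), summing to 1 per sample;
* **Shannon entropy** — for group members with fractional contributions
  $p_i$, $H = -\sum_i p_i \log_2 p_i$ (bits). $H = 0$ when one feature
  dominates; $H = \log_2 n$ for $n$ equally abundant features. A group
  with zero counts in a sample has no defined composition; the entropy is
  reported missing rather than zero, because "silent" and "maximally
  concentrated" are different states.

Entropy grouping follows the annotation's own hierarchy: biotype for
genes, superfamily (repClass) for repeats. Both the subfamily-level
features and the superfamily-level groupings are exposed, since either
granularity can be of interest.

For PCA and sample correlation the package uses `log2(normalized + 1)`
as its variance-stabilizing transform. This is a deliberate,
documented simplification: it preserves the analysis contract (centred,
scaled input; rank-50 PCA of features with non-zero s.d.) with a closed
form that is exactly reproducible. Z-scores use the `n - 1` standard
deviation, matching the R `scale()` convention.

## Differential expression

`nb_wald_test()` is a transparent negative-binomial Wald test:

1. dispersion per feature by method of moments on normalized counts,
   $\hat\alpha_i = \max(0, (v_i - m_i)/m_i^2)$ so that
   $\mathrm{Var} = \mu + \alpha\mu^2$;
2. per feature, an NB log-linear model
   `~ covariates + condition` (condition last) with a log size-factor
   offset, fit by iteratively reweighted least squares;
3. Wald $z = \beta_{cond}/\mathrm{se}$, two-sided normal $p$,
   Benjamini–Hochberg adjustment over tested features, significance at
   padj < 0.01.

Continuous covariates (age, input volume) are standardized before
fitting — this conditions the fit without changing the condition
coefficient. Non-converged features get a missing p-value and are
excluded from the BH denominator. Relative to full-featured DE packages
there is deliberately **no** dispersion shrinkage, LFC shrinkage,
independent filtering or outlier refitting: each feature is treated
independently, which is statistically conservative at moderate sample
sizes (n = 60 in the simulated cohorts) and keeps every number traceable
to a formula above. Externally computed DE tables in the standard column
dialect (`baseMean`, `log2FoldChange`, `lfcSE`, `pvalue`, `padj`) can be
substituted anywhere a `DEResult` is accepted.

Sample stage is carried in metadata as a stratification label only; it
never enters the design, and gender enters as a plain factor covariate.

## Diagnostic classification

The protocol, per disease-vs-healthy comparison:

1. **Split** 80/20, stratified by condition, deterministic per seed.
2. **Feature sets** — eight canonical matrices in three categories:
   total counts (naive / aware / repeat-alone), DE-filtered counts
   (same three views, with DE computed on the training split only) and
   entropy (clade entropy alone, or plus naive counts). A provenance
   check refuses DE results whose sample set extends beyond the training
   split — the leakage guard is structural, not advisory.
3. **Training** — for each elastic-net mixing value $\alpha \in \{0,
   0.1, \ldots, 1\}$ (ridge to lasso in the standard convention),
   $\lambda$ is chosen by 10-fold cross-validated binomial deviance with
   stratified folds; each candidate is refit on the full training split.
4. **Threshold** — the smallest probability cutoff achieving specificity
   $\ge 0.90$ on training controls (candidates: midpoints between
   distinct control probabilities plus sentinels 0 and 1). "At least
   90% with maximal sensitivity" is the reproducible reading of an
   approximate target given finitely many controls.
5. **Selection** — candidates are ranked by training sensitivity at that
   threshold, ties broken by training AUC, then by smaller $\alpha$; the
   full per-$\alpha$ leaderboard is retained in the fit. When several
   feature sets compete, the same ranking applies across all
   ($\alpha$, feature set) candidates.
6. **Evaluation** — the frozen model (training standardization, training
   threshold) is applied to the held-out split; sensitivity is reported
   with an exact Clopper–Pearson 95% interval. "Binomial confidence
   interval" admits several readings; the exact interval is the
   conservative, assumption-free choice.

Feature standardization always uses training means and standard
deviations, applied unchanged to test data. AUC is the Mann–Whitney
probability with ties counting one half, so it equals the pair-counting
definition exactly.

## Fragment-length analysis

Long-read template lengths give the observed size of each cell-free RNA
molecule. Where an aligned fragment overlaps several annotations
(≥ 1 bp intersection — the simplest defensible candidacy rule), the
annotation whose length is **closest to the fragment's** is chosen;
ties break to the smaller annotation, then lexicographic unit id, making
resolution a total order. Any catalog unit may be a candidate — genes
and repeats alike — with group labels carried through to the summaries.
Per-fragment observed/expected ratios are flagged full-length
(ratio ≥ 0.9) or half-length (0.4–0.6); both windows are configurable
constants, since "full-length" and "half-length" are qualitative
descriptions of the underlying biology (intact elements vs a processed
shorter species).

## The synthetic cohort

The generator's defaults define the study conditions used throughout the
tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| cohort | 30 healthy + 30 disease | desk-scale version of a case/control cfRNA cohort |
| catalog | 30 genes, 5 subfamilies (2 Alu-like SINE, LINE, LTR, simple repeat) | one representative per superfamily |
| planted signal | log2fc = 2 on `rmsk:AluY`, `rmsk:AluSx` | strong Alu-subfamily enrichment in disease |
| dispersion $\alpha$ | 0.2 | moderate biological overdispersion |
| library sizes | log-normal, sd 0.3 | realistic depth variation |
| covariate effects | 0.05–0.1 log2/SD | small nuisance structure for the adjusted model |
| reads | ~2,000 x 50 nt per sample, 10% unassignable background | minutes on one CPU |
| SINE fragment lengths | 0.5 N(300, 20²) + 0.5 N(150, 15²), truncated > 0 | bimodal full-/half-length Alu RNA |

Reads are drawn as exact substrings of strand-resolved unit sequences,
so the toy quantifier (exact substring matching, multi-hits split
equally) recovers them by construction; this isolates the aggregation
and statistics from alignment error. What the generator does **not**
emulate: sequencing error and quality, splicing (toy transcripts span
their locus), chimeric reads, realistic repeat genomic density, and
polymorphic insertions. Passing tests therefore validate the catalog
logic, the estimators and the classification protocol — not robustness
to alignment artefacts in real data.

Randomness is a single stream keyed by the configuration seed, with
per-stage sub-seeds derived deterministically, so every fixture is
byte-reproducible.

## Numerical choices and degenerate inputs

* Size factors are undefined when no feature is positive in all samples;
  this errors with a pointer to a pseudo-reference fallback rather than
  silently proceeding.
* The Wilcoxon wrapper uses the exact null (enumeration) when both
  groups have ≤ 8 observations and no ties, else the tie-corrected
  normal approximation; an all-zero paired difference vector returns
  p = 1 with a warning.
* A model regularized to all-zero coefficients predicts a constant; the
  threshold machinery then yields specificity 1 / sensitivity 0 rather
  than failing.
* With fewer than 10 controls a 90% specificity threshold is
  coarse-grained; the function warns but proceeds.
* K-means for heatmap ordering defaults to k = 2 with multiple restarts
  under a fixed seed (exposed through the matrix/z-score outputs; no
  plot rendering is included).

## Problem sizes

The bundled validation runs use: 60-sample cohorts; 2,000 features for
null-calibration of the DE test; 10 pipeline seeds for end-to-end
recovery; 2,000 fragments for the length analysis; 1,000-case oracles
for resolution and entropy bounds. These sizes give Monte-Carlo error
comfortably inside the asserted tolerances while completing in minutes
on a single CPU.

## Known limitations

* The DE surrogate's per-feature dispersion is noisy at small n; shrunken
  estimators will be better powered on real cohorts. The import path for
  external DE tables exists for exactly this reason.
* Subfamily aggregation assumes the instance-to-subfamily map is correct
  and complete; novel or polymorphic insertions are out of scope.
* The toy quantifier is not an aligner; it exists to make ground truth
  exact, not to model mapping ambiguity realistically.
* Probabilities from the elastic-net models are not calibrated; only
  their ranking and the specificity-anchored threshold are used.
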