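# cfrepeat

Repeat-aware profiling of cell-free RNA, and diagnostic classification
from repeat-derived signal.

## What problem this solves

Cell-free RNA in blood plasma carries transcripts from transposable
elements and other repeats (SINE/Alu, LINE, LTR, simple repeats), but
conventional gene-only references discard the reads these produce, and
the ~5 million individual repeat insertions in a mammalian genome are far
too many (and too mutually similar) to use as features directly.
`cfrepeat` builds a **repeat-aware feature catalog** that treats each
repeat instance as a "transcript" of its subfamily "gene":

```
instance  AluY:chr1:100-406(+)   ─┐
instance  AluY:chr7:2001-2307(-) ─┼──►  feature  rmsk:AluY
instance  AluY:chrX:88-394(+)    ─┘
```

so millions of instances collapse to ~10⁴ subfamily features that sit
alongside annotated genes in one count matrix. On top of that catalog the
package provides, for case/control liquid-biopsy cohorts:

* **aggregation** of quant.sf-dialect tables to feature counts, with
  repeat-naive vs repeat-aware mapping-rate comparison (paired Wilcoxon);
* **composition statistics** — per-sample group fractions and Shannon
  entropy *H* = −Σ pᵢ log₂ pᵢ over each biotype / repeat superfamily;
* **differential expression** — per-feature negative-binomial Wald test
  with covariate adjustment (`~ age + gender + input_volume + condition`),
  method-of-moments dispersion, BH correction, significance at padj < 0.01;
* **diagnostic classifiers** — elastic-net logistic regression
  (α grid 0…1, λ by 10-fold CV deviance), model selection by training
  sensitivity at the **90%-specificity probability threshold**, held-out
  evaluation with exact binomial CIs, and a structural guard against
  DE-feature leakage from the test split;
* **fragment-length analysis** for long reads — overlapping annotations
  resolved by closest length, per-group medians, bimodal-mode detection
  and full-/half-length calling;
* a **synthetic-data module** (toy genome with planted repeat instances,
  exact-match toy quantifier, NB count cohorts with planted fold changes,
  bimodal fragment sets) so the entire pipeline is testable with known
  ground truth.

Intended users: computational biologists working on liquid-biopsy
transcriptomics who want repeat-derived signal as first-class features.

## Worked example

The driver runs every stage on a synthetic 60-sample cohort with a
planted Alu enrichment (log2fc = 2 on `rmsk:AluY` and `rmsk:AluSx` in
disease):

```r
library(cfrepeat)
res <- run_pipeline(seed = 1)

res$fit
#> ModelFit [de_aware]: alpha=0, lambda=0.0488, 2/2 non-zero features
#>   training sens=1 @ spec=0.917, AUC=1, threshold=0.09041

res$eval$sensitivity                # held-out, at the training threshold
#> [1] 1
res$eval$ci_low                     # exact binomial CI on 6 test cases
#> [1] 0.5407419

mean(res$mapping$aware); mean(res$mapping$naive)
#> [1] 0.9003159
#> [1] 0.7368834
res$mapping$test$p_value            # paired two-sided Wilcoxon
#> [1] 1.671329e-11

subset(res$de, !is.na(padj) & padj < 0.01)$feature
#> [1] "rmsk:AluY" "rmsk:AluSx"
```

Reading this: the repeat-aware reference assigns ~90% of reads versus
~74% for the gene-only reference (the gap is exactly the repeat-derived
read mass); the training-split DE recovers precisely the two planted
subfamilies at padj < 0.01; the elastic-net model built on those DE
features classifies all held-out samples correctly at the probability
threshold that achieved ≥ 90% specificity in training.

Individual stages are ordinary functions (`parse_rmsk()`,
`build_catalog()`, `aggregate_counts()`, `shannon_entropy()`,
`nb_wald_test()`, `cv_train()`, `annotate_fragments()`, …) and a thin
command-line front end wraps them:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","cfrepeat.R",package="cfrepeat"))') run-all --seed 1 --out out/
```

## Layout

```
R/                  annotation, quantify, features, diffexp, classify,
                    lengths, synthetic, pipeline
inst/cli/           command-line front end
scripts/            acceptance.R
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette (models, parameters, design choices)
```
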