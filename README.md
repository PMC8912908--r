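# cardiosplice

Detection and characterization of developmental stage-specific isoform
switching in cardiovascular bulk RNA-seq, and quantification of the
reversion of heart-failure transcriptomes toward a fetal-like isoform
program.

## Who this is for

Failing adult hearts partially reactivate a fetal gene program. Measuring
that transcriptome-wide requires comparing fetal-like, healthy adult and
heart-failure samples at the *isoform* level while controlling for the very
different cell-type compositions of bulk samples. cardiosplice is for
computational biologists who want that full chain as tested, reusable R
functions: isoform-usage preprocessing, covariate-adjusted differential
expression, tissue-specificity calls, exon sequence analyses, eCLIP peak
enrichment, cell-type deconvolution, ridge regression with collinear
proportion covariates, and the heart-failure reversion statistic — plus a
synthetic-cohort generator with ground-truth labels so every stage can be
validated without controlled-access data.

## The core models

* **Differential usage.** Per feature, OLS of the rank inverse-normal
  transformed phenotype on a tissue indicator and four technical
  covariates (sex, z-scored read count, % autosomal, % mitochondrial
  reads); Bonferroni within each comparison. A feature is
  *tissue-specific* when adjusted p < 0.05 and the original-scale means
  satisfy |log2((m1+c)/(m2+c))| > 2.
* **Ridge DE with proportions.** Cell-type proportions sum to one, so the
  stage effect conditional on composition is fit by ridge regression:
  β̂ = (XᵀX+λI)⁻¹XᵀY, λ by generalized cross-validation, sandwich standard
  errors, normal p-values.
* **Deconvolution.** Signature matrix of single-cell marker means; per
  sample, NNLS-calibrated joint z-scoring and nu-SVR (or NNLS) with
  negative-coefficient truncation and simplex renormalization.
* **Reversion odds ratio.** Over a shared isoform universe, the 2x2 table
  of (DE in heart failure vs healthy heart) x (DE in fetal-like vs healthy
  heart with the same effect sign), tested with Fisher's exact test
  (conditional-MLE odds ratio).

The methods vignette (`vignettes/cardiosplice-methods.Rmd`) documents every
model, default and degenerate-input rule.

## Worked example

Simulate the default cohort (40 fetal-like iPSC-CVPC, 40 adult heart, 30
adult arteria, 8 pre/post-LVAD pairs; 2,000 genes; 250 planted isoform
switches) and call stage-specific isoforms:

```r
library(cardiosplice)

cohort <- simulateCohort(simConfig(seed = 1))
cohort
#> SimulatedCohort: 2000 genes, 3962 isoforms, 126 samples

usage <- computeIsoformUsage(cohort$iso_tpm, cohort$annotation)
kept  <- filterExpressedIsoforms(usage, cohort$annotation)
norm  <- inverseNormalTransform(kept$matrix)
de    <- fitLinearDE(norm, cohort$samples, "iPSC-CVPC", "adult_heart")
de    <- classifySpecific(de, kept$matrix, cohort$samples,
                          "iPSC-CVPC", "adult_heart")
table(de$class)
#>           not_DE tissue1_specific tissue2_specific
#>             2289              250              250
```

The 250 + 250 specific isoforms are exactly the planted reciprocal switch
pairs (`cohort$truth$switch_isoforms`): each switching isoform moves from
5% usage in one stage to 35–65% in the other, e.g.

```r
head(de[de$class == "tissue1_specific",
        c("feature_id", "effect", "p_adj", "log2_ratio")], 3)
#>    feature_id   effect        p_adj log2_ratio
#> 9    G00006.1 1.638169 1.033177e-15   3.110891
#> 17   G00008.1 1.675742 5.453765e-18   3.155002
#> 28   G00021.1 1.587431 1.275378e-17   2.554147
```

`effect` is the tissue coefficient on the normalized scale, `log2_ratio`
the original-scale usage ratio with a 0.01 pseudocount — here 2.5–3.2, i.e.
a 6–9-fold usage shift toward the fetal-like stage.

`runPipeline(list(seed = 1, outdir = "out"))` chains every stage
(preprocess → DE → deconvolution → ridge → exon/eCLIP/motif analyses →
heart failure) and writes each result as a TSV with a JSON provenance
sidecar; reruns with the same configuration are byte-identical.

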