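---
title: "Models and methods in cardiosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cardiosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Failing adult hearts partially reactivate a fetal gene program: genes and
transcript isoforms characteristic of fetal cardiac tissue reappear in heart
failure. Studying this transcriptome-wide is hard because bulk RNA-seq mixes
cell types with very different expression programs, and fetal cardiac tissue
is rarely available; induced pluripotent stem cell-derived cardiovascular
progenitor cells (iPSC-CVPC) serve as a fetal-like surrogate. cardiosplice
implements the complete analytical chain for this setting:

1. filter and normalize gene- and isoform-level TPM matrices, and work with
   *isoform usage* (the fraction of a gene's isoform-level expression carried
   by one isoform) rather than isoform TPM, because usage is independent of
   transcript length;
2. covariate-adjusted differential expression and differential isoform usage
   between tissue groups (fetal-like vs adult heart vs adult arteria);
3. classification of features as *tissue-specific* (> 4-fold mean difference
   at Bonferroni-corrected significance);
4. derivation of tissue-specific exon sets from reciprocally specific
   isoforms, and their sequence characterization: protein-domain overlap,
   positional splice-site nucleotide composition, polypyrimidine tracts, and
   RNA-binding-protein (RBP) motif occurrence in acceptor-side windows;
5. enrichment of RBP eCLIP binding sites in genes with tissue-specific
   isoforms, swept over 13 effect-size cutoffs;
6. cell-type deconvolution of bulk samples against a single-cell derived
   signature matrix, and ridge-regression differential expression that
   includes the (collinear) cell-type proportions as covariates;
7. a heart-failure stage: joint PCA of RBP expression across healthy and
   pre/post-LVAD samples, PC-space distances with paired tests, a one-sample
   location test on RBP effect sizes, and a fetal-reversion odds ratio for
   isoforms.

Every stage is testable without controlled-access data because the package
ships a synthetic-cohort generator that plants all of the structure above and
records it as ground truth.

# The statistical models

## Differential expression and usage

For each feature the model is ordinary least squares of the normalized
phenotype on a tissue indicator plus four technical covariates: sex, z-scored
total read count, fraction of autosomal/sex-chromosome reads, and fraction of
mitochondrial reads (mitochondria-rich cell types depress nuclear TPM values,
so these are genuine confounders). The tissue effect is tested with the
single-coefficient t-test, which is identical to the one-coefficient F-test;
p-values are Bonferroni-corrected within each pairwise comparison. The
phenotype is first transformed per feature by the rank inverse-normal map
`qnorm((rank - 0.5)/n)`, which realizes "mean 0, sd 1 per feature" exactly
and is invariant to monotone changes of the raw scale.

Tissue specificity is decided on the *original* scale: with group means
$m_1, m_2$ and pseudocount $c$ (1 TPM for genes, 0.01 for usage fractions),
a feature is tissue1-specific iff Bonferroni-adjusted $p < 0.05$ and
$\log_2\frac{m_1 + c}{m_2 + c} > 2$, strictly. The pseudocounts are the
package's choice: they keep zero means finite while preserving the
">4-fold" reading for well-expressed features.

## Ridge regression with cell-type proportions

Cell-type proportions sum to one, so adding all six to an OLS design with an
intercept is singular. The package fits ridge regression instead: predictors
standardized, coefficients $(X^\top X + \lambda I)^{-1} X^\top y$ with
$\lambda$ chosen per feature by generalized cross-validation on a 25-point
log grid $10^{-4}..10^{4}$. Standard errors use the linear-smoother sandwich
$\hat\sigma^2 (X^\top X+\lambda I)^{-1} X^\top X (X^\top X+\lambda I)^{-1}$
with $\hat\sigma^2 = RSS/(n - \mathrm{tr}(H) - 1)$ (the $-1$ accounts for
the intercept absorbed by centering), and two-sided normal p-values. This is
an approximation — no bias-corrected projection is attempted — guarded by a
test that the $\lambda = 0$ limit reproduces classical OLS to 1e-8. Effects
are reported on the standardized-predictor scale; comparisons with OLS
effect sizes are therefore scale-sensitive.

## Gene-set procedures

Two complementary procedures: (i) effect-size GSEA — per gene set, a Welch
t-test of in-set versus out-of-set DE effect sizes, BH-corrected across
sets; (ii) for genes with tissue-specific isoforms, a 2x2 Fisher exact test
of set membership against genes with no DE isoform at all (genes with DE but
non-specific isoforms are excluded from both groups).

## Exon sets and sequence analyses

Tissue-specific exons are derived only from genes carrying at least one
specific isoform on *each* side; exon identifiers are shared between
isoforms when coordinates coincide, so the per-side exon sets are plain set
differences. Windows are always taken in transcription orientation: the
acceptor window is the 100 nt upstream of the exon start, the donor window
the 100 nt downstream of the exon end. Positional composition is compared
with per-position, per-nucleotide Fisher tests, BH-corrected across
positions and nucleotides within each side (this family uses FDR control,
unlike the Bonferroni used for feature-level DE). Windows truncated at a
chromosome edge contribute only their covered positions.

Motif occurrence replaces an external motif-discovery tool with a defined,
fully testable procedure: a window "contains" a motif when the maximum
log-odds score of the PWM against a uniform background (sense strand only —
the motifs bind RNA) reaches 80% of the motif's maximum attainable score;
PWM probabilities are floored at 0.01 before taking log-odds so single zero
entries cannot veto a window. Per motif, one-sided Fisher tests are run in
both directions and the direction with the smaller BH q is kept, with the
log2 ratio of containment proportions (Haldane-corrected) signed positive
for the first set. First exons of every isoform are excluded from the motif
analysis only, not from the splice-site tests, since promoter-proximal
sequence is not an acceptor context.

## eCLIP threshold sweep

At each cutoff $\tau \in \{0, 0.5, ..., 6\}$ the "specific" genes of a
direction are those owning at least one DE isoform (FDR < 0.05) with
$|\log_2$ ratio$|$ beyond $\tau$; a gene qualifying in both directions is
assigned to the direction of its largest-$|\log_2$ ratio$|$ isoform. The
background is genes with *no* DE isoform; genes with DE isoforms failing
the cutoff sit on neither side. Per eCLIP experiment, a Fisher test
contrasts the fractions of gene bodies overlapping at least one peak
(strand-blind, >= 1 bp). Interval overlaps throughout the package are
strand-blind because eCLIP peak files do not reliably encode the bound
strand; sequence windows, in contrast, are always strand-aware.

## Deconvolution

Markers come from one-vs-rest Wilcoxon tests on log-normalized single-cell
counts (counts per 10,000, log1p), kept when the shift is positive,
detection is >= 20% of in-type cells, log2 fold change >= 0.1 and
Bonferroni-adjusted p < 0.1. The signature matrix is the mean depth-scaled
(un-logged) expression of the markers per type. Proportion estimation
re-implements the published support-vector core rather than calling an
external service: per sample the mixture is first scale-calibrated by a
nonnegative least-squares pass (mixture and signature units generally
differ), mixture and signature are then z-scored jointly against their
pooled values — never quantile-mapped — and nu-SVR (linear kernel, nu in
{0.25, 0.5, 0.75}, best RMSE kept) or NNLS is solved; negative coefficients
are truncated and the rest renormalized to the simplex. NNLS is the
deterministic fallback and the cross-check: both solvers must agree on
noiseless mixtures.

## Heart-failure stage

RBP-panel PCA is a joint PCA on z-scored log2(TPM+1) of all samples
(healthy and heart failure together), with the sign of each component fixed
by its largest-|loading| RBP. This deliberately replaces reference-anchored
integration: the question — are pre-LVAD samples closer to the fetal-like
group and post-LVAD samples closer to the adult group in RBP expression
space — is geometric, and joint PCA answers it deterministically. Published
distance p-values obtained under anchor integration are therefore not
comparable targets. Distances are mean Euclidean distances in the top-10 PC
space to every sample of each healthy group, compared pre vs post by paired
t-test (pairs with zero difference variance are reported as p = 1 for zero
shift, p = 0 otherwise).

The fetal-reversion statistic takes two DE runs over the same isoform
universe — heart failure vs healthy adult heart, and fetal-like vs healthy
adult heart — and forms the 2x2 table A = DE in both with the same effect
sign, B = HF-DE otherwise, C = not HF-DE but fetal-DE with the same effect
sign, D = remainder, with the conditional-MLE odds ratio and exact p from
Fisher's test, plus the Pearson correlation of the two effect vectors. The
same-trend condition applies to both rows deliberately: that makes the odds
ratio exactly 1 under independence of the two comparisons (verified by
null simulation), a property no single-row-conditioned table has. The
published account of this table is ambiguous about how the margins were
formed; the definition above is the package's own, fixed and validated
against synthetic ground truth, where the odds ratio is strictly increasing
in the planted reversion fraction.

# The synthetic cohort

`simConfig()` defaults encode the study conditions: 40 fetal-like, 40 adult
heart and 30 adult arteria samples plus 8 paired pre/post-LVAD subjects;
2,000 genes, half with 2-4 isoforms; 300 stage-DE genes with
$|\log_2 FC| \sim U(2.5, 4)$ concentrated in a designated 120-gene RBP
panel that is fetal-biased (85% of its effects are fetal-up); 250 switch
isoform pairs with usage shift $\Delta \sim U(0.3, 0.6)$; half of the
switch pairs reverting toward fetal usage in pre-LVAD samples (at 75% of
the fetal-adult gap); and multiplicative lognormal noise with sd 0.25 on
the log2 scale — a noise model chosen because it preserves nonnegativity
and realistic heteroskedasticity.

Gene TPM is a mixture: per sample, cell-type proportions are drawn from a
per-tissue Dirichlet (the fetal-like tissue carries almost no fibroblast or
immune mass), multiplied through a gene-by-cell-type signature with
30 markers per type at 16-fold elevation, then by the stage effect and
noise. Isoform TPMs partition the gene TPM through a per-sample Dirichlet
draw around the tissue's usage target (concentration 150), so isoform TPMs
sum exactly to the gene TPM. Switch genes have at least three isoforms so
the switching pair can be reciprocally minor (usage 0.05) and major
(0.05 + $\Delta$) — a genuine reciprocal switch in which both pair members
clear the 4-fold specificity threshold. A disjoint set of 150 pairs
switches only in pre-LVAD samples, modeling disease-specific splicing
unrelated to the fetal program; without it the reversion table would be
degenerate at reversion fraction 0. Markers are excluded from the stage-DE
pool so that composition shifts and stage effects remain separable; with
16-fold markers and the default proportions, composition-driven fold
changes stay below the 4-fold specificity threshold, which is what makes
"zero false specific calls" a meaningful check.

The annotation places each gene's exons (4 shared + one unique cassette
exon per isoform, all internal) on a synthetic genome (one chromosome per
100 genes); canonical GT/AG dinucleotides are planted at 80% of exon
boundaries. eCLIP-like peaks land in switch-gene bodies with probability
0.6 versus 0.3 elsewhere; one motif consensus is planted in 60% of
fetal-specific versus 20% of adult-specific acceptor windows; domains
overlap 60% versus 35% of the specific exons. The single-cell fixture draws
negative-binomial counts (dispersion 0.5, 200 cells per type) from the same
signatures. A separate generator, `simulateSpliceSets()`, builds exon sets
with exact per-position base compositions for the splice-site tests.

What the generator does *not* emulate: read-level sampling (no FASTQ, no
mapping bias), correlated noise across genes, isoform structures more
complex than shared-plus-cassette, batch structure within a tissue, and
real genome sequence. Passing recovery tests therefore demonstrates the
statistical machinery is correct under the declared generative model, not
that real cohorts meet its assumptions.

# Numerical choices and degenerate inputs

* Filters follow the printed wording exactly: gene expression TPM >= 1
  (inclusive) in at least ceil(10% n) samples; isoform usage > 10%
  (strict); genes keep at least two expressed isoforms or are dropped. The
  isoform filter runs after the gene filter.
* Zero-denominator usage (gene unexpressed in a sample) is 0 with a flag,
  keeping matrices dense; constant features transform to all-zero with a
  flag.
* Exact 2x2 tests ride on `fisher.test` (conditional-MLE odds ratio); a
  test-side oracle re-derives both the p-value and the MLE by exhaustive
  enumeration of tables with fixed margins.
* Ties in the eCLIP direction assignment (equal |log2 ratio| both ways) go
  to direction 1; feature output ordering is lexicographic everywhere, so
  outputs are byte-stable.
* All randomness flows from one integer seed; cohort components draw from
  per-component seed streams, so generating a subset of components never
  changes the others.

# Problem sizes used by the test suite

The acceptance checks run at the generator defaults except where a smaller
size already determines the answer: the reversion-monotonicity sweep uses
1,000-gene cohorts (scaling the planted fractions with the default ratios)
over 20 seeds per reversion fraction, the null reversion calibration uses
5,000-isoform label simulations, positional-test power uses 400 exons per
side over 100 seeds, and the end-to-end determinism check runs the full
default cohort twice. These sizes are the package's choices for a
single-CPU test run and are stated here so they can be scaled up.

# Known limitations

* The rank inverse-normal transform has a discrete, bounded marginal; at
  Bonferroni-scale thresholds (e.g. 0.05/2000) the per-feature t-test on
  transformed data is mildly anti-conservative with 40+40 samples (measured
  family-wise error ~0.07 at nominal 0.05 on null cohorts, against an exact
  matched-normal control). At the nominal 0.05 level calibration is exact
  within Monte-Carlo error.
* Ridge inference is approximate (sandwich, normal p); it is validated at
  the OLS limit and by recovery, not against a projection estimator.
* The motif procedure is a containment test, not a de-novo motif finder;
  its threshold (80% of maximal score) is a fixed design constant.
* The reversion table definition is one of several consistent with the
  published counts; cross-study comparability of its absolute value is
  limited, monotonicity in the underlying reversion fraction is what the
  package guarantees.
* nu-SVR solutions depend on the SVM library's convergence; NNLS is the
  deterministic reference path used in the orchestrated pipeline when
  byte-stability matters most.
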