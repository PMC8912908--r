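## Independent oracles and tiny fixture builders shared across tests.

## Exhaustive-enumeration oracle for the 2x2 exact test: two-sided p and the
## conditional-MLE odds ratio under the noncentral hypergeometric model, with
## margins fixed. Independent of stats::fisher.test.
fisherOracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  logw <- lchoose(m1, xs) + lchoose(m2, k - xs)
  dens <- function(psi) {
    lp <- logw + xs * log(psi)
    p <- exp(lp - max(lp))
    p / sum(p)
  }
  p1 <- dens(1)
  pobs <- p1[xs == a]
  pval <- sum(p1[p1 <= pobs * (1 + 1e-7)])
  or <- if (a == hi && a == lo) NA_real_
  else if (a == hi) Inf
  else if (a == lo) 0
  else {
    f <- function(logPsi) sum(xs * dens(exp(logPsi))) - a
    exp(stats::uniroot(f, c(-30, 30), tol = 1e-12)$root)
  }
  list(p = pval, or = or)
}

## direct normal-equations oracle for a single feature: coefficient j of the
## OLS fit of y on X with classical SE and two-sided t-test p
olsOracle <- function(y, X, j) {
  XtXinv <- solve(t(X) %*% X)
  beta <- XtXinv %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(s2 * diag(XtXinv))
  t <- beta[j] / se[j]
  c(beta = beta[j], se = se[j],
    p = 2 * stats::pt(-abs(t), nrow(X) - ncol(X)))
}

## minimal two-gene annotation: geneA (+, 2 isoforms sharing e1/e3) and
## geneB (-, 1 isoform)
tinyAnnotation <- function() {
  ex <- GenomicRanges::GRanges(
    c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    IRanges::IRanges(c(101, 301, 501, 701, 101, 501),
                     c(200, 400, 600, 800, 200, 600)),
    strand = c("+", "+", "+", "+", "-", "-"))
  names(ex) <- c("eA1", "eA2", "eA3", "eA4", "eB1", "eB2")
  genes <- data.frame(gene_id = c("geneA", "geneB"),
                      gene_name = c("geneA", "geneB"),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  new("TranscriptAnnotation", genes = genes,
      transcripts = list(geneA.1 = c("eA1", "eA2", "eA3", "eA4"),
                         geneA.2 = c("eA1", "eA3"),
                         geneB.1 = c("eB2", "eB1")),
      txGene = c(geneA.1 = "geneA", geneA.2 = "geneA", geneB.1 = "geneB"),
      exons = ex)
}

## deterministic toy genome: one chromosome of repeated ACGT
tinyGenome <- function(len = 1200, chrom = "chr1") {
  s <- paste(rep(c("A", "C", "G", "T"), length.out = len), collapse = "")
  g <- Biostrings::DNAStringSet(s)
  names(g) <- chrom
  g
}

## sample table for n1 + n2 samples in two tissues
twoTissueSamples <- function(n1, n2, t1 = "iPSC-CVPC", t2 = "adult_heart",
                             seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    subject_id = sprintf("SUBJ%03d", seq_len(n)),
    tissue = rep(c(t1, t2), c(n1, n2)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    total_reads = round(stats::rlnorm(n, log(3e7), 0.2)),
    pct_autosomal = stats::runif(n, 0.7, 0.9),
    pct_mito = stats::runif(n, 0.05, 0.2),
    stringsAsFactors = FALSE)
}

## a small expression-only cohort used by several module tests
smallCohort <- function(seed = 11, ...) {
  simulateCohort(simConfig(n_ipsc = 15, n_heart = 15, n_arteria = 10,
                           n_hf_pairs = 4, n_genes = 300, n_stage_de = 40,
                           n_rbp = 20, n_switch = 25, n_hf_switch = 15,
                           markers_per_type = 10, sc_cells_per_type = 40,
                           n_gene_sets = 8, seed = seed, ...),
                 components = character(0))
}
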