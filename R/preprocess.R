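## Expression/usage filtering, isoform-usage computation, rank inverse-normal
## transformation, and the read-length blacklist.

#' Filter genes by expression
#'
#' Retains genes with TPM >= \code{min_tpm} (inclusive) in at least
#' \code{ceiling(min_frac * n_samples)} samples.
#'
#' @param tpm a \linkS4class{FeatureMatrix} of kind "tpm".
#' @param min_tpm TPM threshold (inclusive).
#' @param min_frac minimum fraction of samples.
#' @return list with \code{matrix} (the filtered \linkS4class{FeatureMatrix})
#'   and \code{report} (input/retained counts, criterion, per-feature flags).
#' @export
filterExpressedGenes <- function(tpm, min_tpm = 1, min_frac = 0.10) {
  stopifnot(is(tpm, "FeatureMatrix"), matrixKind(tpm) == "tpm")
  v <- as.matrix(tpm)
  if (!nrow(v) || !ncol(v)) stop("empty matrix")
  need <- ceiling(min_frac * ncol(v))
  pass <- rowSums(v >= min_tpm) >= need
  list(matrix = tpm[pass, ],
       report = list(n_input = nrow(v), n_expressed = sum(pass),
                     criterion = sprintf("TPM >= %g in >= %d of %d samples",
                                         min_tpm, need, ncol(v)),
                     pass = pass))
}

#' Compute isoform usage fractions
#'
#' usage(i, s) = TPM(i, s) / sum of TPM over all isoforms of the gene of i in
#' sample s; samples where the gene's isoform TPMs sum to zero get usage 0
#' for every isoform (flagged in the \code{zero_denominator} attribute).
#' Usage is preferred over isoform TPM because it is independent of
#' transcript length and therefore comparable across samples.
#'
#' @param iso_tpm isoform-level \linkS4class{FeatureMatrix} (kind "tpm").
#' @param ann a \linkS4class{TranscriptAnnotation}; every isoform id must map
#'   to a gene.
#' @return \linkS4class{FeatureMatrix} of kind "usage" with attribute
#'   \code{zero_denominator} (logical gene x sample flags, genes with any
#'   zero-sum sample only).
#' @export
computeIsoformUsage <- function(iso_tpm, ann) {
  stopifnot(is(iso_tpm, "FeatureMatrix"))
  v <- as.matrix(iso_tpm)
  txg <- txToGene(ann)
  missing <- setdiff(rownames(v), names(txg))
  if (length(missing))
    stop("isoform(s) absent from annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  gene <- txg[rownames(v)]
  ## per gene per sample denominator
  denom <- rowsum(v, gene)                     # genes x samples
  d <- denom[gene, , drop = FALSE]
  usage <- ifelse(d > 0, v / d, 0)
  dimnames(usage) <- dimnames(v)
  out <- FeatureMatrix(usage, "usage")
  zero <- denom == 0
  attr(out@values, "zero_denominator") <- zero[rowSums(zero) > 0, ,
                                               drop = FALSE]
  out
}

#' Filter isoforms by usage
#'
#' An isoform is expressed iff usage > \code{min_usage} (strictly) in at
#' least \code{ceiling(min_frac * n)} samples; genes retaining fewer than two
#' expressed isoforms are removed entirely.
#'
#' @param usage a \linkS4class{FeatureMatrix} of kind "usage".
#' @param ann a \linkS4class{TranscriptAnnotation} (isoform -> gene map).
#' @param min_usage usage threshold (strict).
#' @param min_frac minimum fraction of samples.
#' @return list with \code{matrix} and \code{report} as in
#'   \code{\link{filterExpressedGenes}}.
#' @export
filterExpressedIsoforms <- function(usage, ann, min_usage = 0.10,
                                    min_frac = 0.10) {
  stopifnot(is(usage, "FeatureMatrix"), matrixKind(usage) == "usage")
  v <- as.matrix(usage)
  need <- ceiling(min_frac * ncol(v))
  expressed <- rowSums(v > min_usage) >= need
  gene <- txToGene(ann)[rownames(v)]
  nExpr <- tapply(expressed, gene, sum)
  keepGene <- names(nExpr)[nExpr >= 2]
  pass <- expressed & gene %in% keepGene
  list(matrix = usage[pass, ],
       report = list(n_input = nrow(v), n_expressed = sum(pass),
                     criterion = sprintf(
                       "usage > %g in >= %d of %d samples; >= 2 isoforms/gene",
                       min_usage, need, ncol(v)),
                     pass = pass))
}

#' Rank inverse-normal transform per feature
#'
#' Replaces each feature's values by qnorm((rank - 0.5) / n) with average
#' ranks for ties, giving every feature mean ~0 and a common, n-dependent
#' spread; this realizes the goal of quantile normalization to a standard
#' normal. Constant features are set to all zeros and flagged.
#'
#' @param m a \linkS4class{FeatureMatrix} with >= 3 samples.
#' @return \linkS4class{FeatureMatrix} of kind "normalized"; attribute
#'   \code{constant_features} lists all-tied features.
#' @export
inverseNormalTransform <- function(m) {
  stopifnot(is(m, "FeatureMatrix"))
  v <- as.matrix(m)
  if (ncol(v) < 3) stop("need >= 3 samples")
  n <- ncol(v)
  out <- t(apply(v, 1, function(x) stats::qnorm((rank(x) - 0.5) / n)))
  const <- apply(v, 1, function(x) max(x) == min(x))
  out[const, ] <- 0
  dimnames(out) <- dimnames(v)
  res <- FeatureMatrix(out, "normalized")
  attr(res@values, "constant_features") <- rownames(v)[const]
  res
}

#' Read-length blacklist via paired t-tests
#'
#' Compares full-length against 3'-trimmed quantifications of the same
#' samples with a per-feature paired t-test, Bonferroni-corrected. A gene is
#' blacklisted if it, or any of its isoforms, differs significantly --
#' features whose quantification depends on read length cannot be compared
#' across cohorts sequenced at different lengths.
#'
#' @param full,trimmed \linkS4class{FeatureMatrix} objects (gene or isoform
#'   level, matched sample columns).
#' @param ann optional \linkS4class{TranscriptAnnotation}; when given,
#'   feature ids found in its transcript map are treated as isoforms and
#'   propagate to their gene.
#' @param alpha Bonferroni-adjusted significance level.
#' @return list with \code{blacklist} (gene ids), \code{features}
#'   (significant feature ids) and \code{p_adj}.
#' @export
readLengthBlacklist <- function(full, trimmed, ann = NULL, alpha = 0.05) {
  vf <- as.matrix(full); vt <- as.matrix(trimmed)
  if (!identical(sort(colnames(vf)), sort(colnames(vt))))
    stop("sample columns differ between full and trimmed matrices")
  vt <- vt[, colnames(vf), drop = FALSE]
  common <- intersect(rownames(vf), rownames(vt))
  d <- vf[common, , drop = FALSE] - vt[common, , drop = FALSE]
  n <- ncol(d)
  mu <- rowMeans(d)
  sdv <- sqrt(rowSums((d - mu)^2) / (n - 1))
  tstat <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[sdv == 0 & mu == 0] <- 1           # identical pairs: no evidence
  p[sdv == 0 & mu != 0] <- 0           # constant nonzero shift
  padj <- pmin(p * length(p), 1)
  sigFeat <- common[padj < alpha]
  genes <- sigFeat
  if (!is.null(ann)) {
    txg <- txToGene(ann)
    iso <- sigFeat %in% names(txg)
    genes <- unique(c(sigFeat[!iso], unname(txg[sigFeat[iso]])))
  }
  list(blacklist = sort(genes), features = sigFeat,
       p_adj = stats::setNames(padj, common))
}
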