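## Covariate-adjusted differential expression/usage: vectorized OLS across
## features, ridge regression with GCV-chosen penalty for collinear cell-type
## proportions, specificity classification, and the two gene-set procedures.

#' Build the technical-covariate design block
#'
#' Covariates follow the standard bulk RNA-seq bias set: sex, z-scored total
#' read count, fraction of autosomal/sex-chromosome reads, fraction of
#' mitochondrial reads.
#'
#' @param samples sample table (data.frame) for the modeled samples.
#' @return numeric matrix with columns sexM, total_reads_z, pct_autosomal,
#'   pct_mito.
#' @export
covariateMatrix <- function(samples) {
  tr <- samples$total_reads
  trz <- if (stats::sd(tr) > 0) (tr - mean(tr)) / stats::sd(tr) else tr * 0
  cbind(sexM = as.numeric(samples$sex == "M"),
        total_reads_z = trz,
        pct_autosomal = samples$pct_autosomal,
        pct_mito = samples$pct_mito)
}

## Vectorized OLS of every feature on a shared design; returns the requested
## coefficient with classical SE / t / p.
.olsAcross <- function(Y, X, coefName) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  B <- qr.coef(qrX, t(Y))                      # p x features
  resid <- t(Y) - X %*% B
  rss <- colSums(resid^2)
  sigma2 <- rss / (n - p)
  XtXinv <- chol2inv(qr.R(qrX))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  j <- match(coefName, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  beta <- B[j, ]
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - p)
  ## zero residual variance (e.g. constant responses): no valid test
  pval[se == 0] <- NA_real_
  data.frame(feature_id = rownames(Y), effect = beta, se = se, t = tstat,
             p = pval, row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise differential expression / usage by linear model
#'
#' Per feature, OLS of the normalized phenotype on an intercept, a tissue
#' indicator (tissue1 = 1, tissue2 = 0, so the effect is tissue1 minus
#' tissue2) and the four technical covariates. Two-sided p-values come from
#' the single-coefficient t-test (equivalent to the one-coefficient F-test);
#' Bonferroni correction is applied over all features tested in the
#' comparison.
#'
#' @param norm normalized \linkS4class{FeatureMatrix}.
#' @param samples sample table covering the matrix columns.
#' @param tissue1,tissue2 tissue labels to compare.
#' @param covariates covariate matrix builder result; defaults to
#'   \code{\link{covariateMatrix}} of the selected samples.
#' @return data.frame (one row per feature): effect, se, t, p, p_adj.
#' @export
fitLinearDE <- function(norm, samples, tissue1, tissue2, covariates = NULL) {
  stopifnot(is(norm, "FeatureMatrix"))
  sel <- samples[samples$tissue %in% c(tissue1, tissue2), , drop = FALSE]
  if (!nrow(sel)) stop("no samples in the requested tissues")
  Y <- as.matrix(norm)[, sel$sample_id, drop = FALSE]
  C <- covariates %||% covariateMatrix(sel)
  X <- cbind(intercept = 1, tissue = as.numeric(sel$tissue == tissue1), C)
  if (nrow(X) <= ncol(X))
    stop("need more samples than design columns (n = ", nrow(X), ", p = ",
         ncol(X), ")")
  res <- .olsAcross(Y, X, "tissue")
  res$p_adj <- pmin(res$p * nrow(res), 1)
  res$comparison <- paste(tissue1, "vs", tissue2)
  res[order(res$feature_id), ]
}

#' Classify features as tissue-specific
#'
#' Group means are computed on the ORIGINAL scale (TPM for genes, usage for
#' isoforms), with a pseudocount keeping zero means finite: log2_ratio =
#' log2((mean1 + c) / (mean2 + c)). A feature is tissue1-specific iff
#' p_adj < alpha and log2_ratio > lr_thresh (strictly); symmetrically for
#' tissue2. Significant features inside the ratio band are "DE_only".
#'
#' @param de result of \code{\link{fitLinearDE}}.
#' @param orig original-scale \linkS4class{FeatureMatrix} (kind "tpm" or
#'   "usage").
#' @param samples sample table.
#' @param tissue1,tissue2 the compared tissue labels.
#' @param lr_thresh log2-ratio threshold (strict).
#' @param alpha adjusted-p threshold.
#' @param pseudocount added to both means; defaults to 1 for TPM and 0.01
#'   for usage fractions.
#' @return \code{de} with columns mean1, mean2, log2_ratio, class.
#' @export
classifySpecific <- function(de, orig, samples, tissue1, tissue2,
                             lr_thresh = 2, alpha = 0.05,
                             pseudocount = NULL) {
  stopifnot(is(orig, "FeatureMatrix"))
  pseudocount <- pseudocount %||%
    if (matrixKind(orig) == "usage") 0.01 else 1
  v <- as.matrix(orig)[de$feature_id, , drop = FALSE]
  s1 <- samples$sample_id[samples$tissue == tissue1]
  s2 <- samples$sample_id[samples$tissue == tissue2]
  de$mean1 <- rowMeans(v[, intersect(s1, colnames(v)), drop = FALSE])
  de$mean2 <- rowMeans(v[, intersect(s2, colnames(v)), drop = FALSE])
  de$log2_ratio <- log2((de$mean1 + pseudocount) / (de$mean2 + pseudocount))
  sig <- !is.na(de$p_adj) & de$p_adj < alpha
  de$class <- ifelse(!sig, "not_DE",
               ifelse(de$log2_ratio > lr_thresh, "tissue1_specific",
               ifelse(de$log2_ratio < -lr_thresh, "tissue2_specific",
                      "DE_only")))
  de
}

#' Ridge differential expression with cell-type proportions
#'
#' Fits Y ~ intercept + tissue + technical covariates + the six cell-type
#' proportions by ridge regression. The proportions sum to one, so the
#' design is collinear by construction; the ridge penalty guarantees a
#' unique, finite solution. Predictors (except the intercept) are
#' standardized; lambda is chosen per feature by generalized cross-validation
#' on a 25-point log grid 1e-4..1e4; standard errors use the linear-smoother
#' sandwich formula sigma^2 (X'X+lI)^-1 X'X (X'X+lI)^-1 with sigma^2 =
#' RSS / (n - tr(H)); p-values are two-sided normal. Effects are reported on
#' the standardized-predictor scale. Bonferroni correction is applied per
#' coefficient family (across features, within each coefficient).
#'
#' @param norm normalized \linkS4class{FeatureMatrix}.
#' @param samples sample table for the modeled samples.
#' @param tissue1,tissue2 tissue labels for the group indicator.
#' @param proportions sample x cell-type matrix of proportions.
#' @param lambda optional fixed penalty (0 reproduces OLS); NULL = GCV.
#' @param coef_names coefficients to report (default: tissue + each cell
#'   type).
#' @return data.frame with one row per feature per reported coefficient:
#'   coefficient, effect, se, p, p_adj, lambda.
#' @export
fitRidgeDE <- function(norm, samples, tissue1, tissue2, proportions,
                       lambda = NULL, coef_names = NULL) {
  stopifnot(is(norm, "FeatureMatrix"))
  sel <- samples[samples$tissue %in% c(tissue1, tissue2), , drop = FALSE]
  if (nrow(sel) < 10) stop("need at least 10 samples")
  Y <- as.matrix(norm)[, sel$sample_id, drop = FALSE]
  P <- proportions[sel$sample_id, , drop = FALSE]
  X0 <- cbind(tissue = as.numeric(sel$tissue == tissue1),
              covariateMatrix(sel), P)
  keep <- apply(X0, 2, function(x) stats::sd(x) > 0)
  X0 <- X0[, keep, drop = FALSE]
  Xs <- scale(X0)
  n <- nrow(Xs); p <- ncol(Xs)
  Yc <- t(Y) - rep(colMeans(t(Y)), each = n)   # center responses; intercept
  XtX <- crossprod(Xs)
  XtY <- crossprod(Xs, Yc)
  grid <- if (is.null(lambda)) 10^seq(-4, 4, length.out = 25) else lambda
  nf <- ncol(Yc)
  gcv <- matrix(Inf, length(grid), nf)
  Blist <- vector("list", length(grid))
  trH <- numeric(length(grid))
  eg <- eigen(XtX, symmetric = TRUE)
  for (i in seq_along(grid)) {
    l <- grid[i]
    Ainv <- eg$vectors %*% (t(eg$vectors) / (eg$values + l))
    B <- Ainv %*% XtY                          # p x features
    trH[i] <- sum(eg$values / (eg$values + l))
    rss <- colSums((Yc - Xs %*% B)^2)
    gcv[i, ] <- rss / (n * (1 - trH[i] / n)^2)
    Blist[[i]] <- B
  }
  best <- apply(gcv, 2, which.min)
  if (is.null(lambda) && any(best %in% c(1L, length(grid))))
    warning("GCV selected a boundary lambda for ",
            sum(best %in% c(1L, length(grid))), " feature(s)")
  coef_names <- coef_names %||% c("tissue", colnames(P))
  coef_names <- intersect(coef_names, colnames(Xs))
  out <- vector("list", length(unique(best)))
  ji <- match(coef_names, colnames(Xs))
  for (u in seq_along(sort(unique(best)))) {
    i <- sort(unique(best))[u]
    l <- grid[i]
    Ainv <- eg$vectors %*% (t(eg$vectors) / (eg$values + l))
    V <- Ainv %*% XtX %*% Ainv                 # sandwich (unit sigma^2)
    feats <- which(best == i)
    B <- Blist[[i]][, feats, drop = FALSE]
    rss <- colSums((Yc[, feats, drop = FALSE] - Xs %*% B)^2)
    sigma2 <- rss / (n - trH[i] - 1)   # -1: intercept absorbed by centering
    out[[u]] <- do.call(rbind, lapply(seq_along(ji), function(k) {
      se <- sqrt(sigma2 * V[ji[k], ji[k]])
      beta <- B[ji[k], ]
      data.frame(feature_id = colnames(Yc)[feats],
                 coefficient = coef_names[k], effect = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)), lambda = l,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  }
  res <- do.call(rbind, out)
  res$p_adj <- NA_real_
  for (cn in coef_names) {
    idx <- res$coefficient == cn
    res$p_adj[idx] <- pmin(res$p[idx] * sum(idx), 1)
  }
  res$comparison <- paste(tissue1, "vs", tissue2)
  res[order(res$coefficient, res$feature_id), ]
}

#' Gene-set enrichment by effect-size t-test
#'
#' Per gene set, a Welch two-sample t-test compares the DE effect sizes of
#' in-set genes against all tested genes outside the set; p-values are
#' Benjamini-Hochberg corrected across sets. Sets with fewer than two
#' members inside the universe, fewer than two genes outside, or identical
#' to the universe are skipped with a warning.
#'
#' @param effects named numeric vector of per-gene effect sizes.
#' @param sets named list of gene-id vectors (see \code{\link{readGmt}}).
#' @return data.frame: set, n_in_set, statistic (t), mean_in, mean_out, p, q.
#' @export
gseaEffectSizeTTest <- function(effects, sets) {
  uni <- names(effects)
  rows <- lapply(names(sets), function(nm) {
    inSet <- intersect(sets[[nm]], uni)
    outSet <- setdiff(uni, inSet)
    if (length(inSet) < 2 || length(outSet) < 2) {
      warning("set skipped (too small or equal to universe): ", nm)
      return(NULL)
    }
    tt <- stats::t.test(effects[inSet], effects[outSet])
    data.frame(set = nm, n_in_set = length(inSet),
               statistic = unname(tt$statistic),
               mean_in = mean(effects[inSet]),
               mean_out = mean(effects[outSet]), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$q <- stats::p.adjust(res$p, "BH")
  res
}

#' Gene-set association of genes with tissue-specific isoforms
#'
#' For each gene set, a 2x2 Fisher exact test contrasts genes owning at
#' least one tissue-specific isoform against genes with no differentially
#' expressed isoform at all (genes with DE-but-not-specific isoforms are
#' excluded from both groups before calling this). Odds ratios are the
#' conditional MLE from \code{fisher.test}; BH correction across sets.
#'
#' @param genes_specific gene ids with a tissue-specific isoform.
#' @param genes_no_de gene ids with no DE isoform (disjoint from
#'   \code{genes_specific}).
#' @param sets named list of gene sets.
#' @return data.frame: set, odds_ratio, p, q, n_in_set.
#' @export
fisherIsoformGeneSet <- function(genes_specific, genes_no_de, sets) {
  if (!length(genes_specific) || !length(genes_no_de))
    stop("both gene groups must be nonempty")
  if (length(intersect(genes_specific, genes_no_de)))
    stop("gene groups must be disjoint")
  uni <- c(genes_specific, genes_no_de)
  rows <- lapply(names(sets), function(nm) {
    mem <- intersect(sets[[nm]], uni)
    if (!length(mem)) return(NULL)               # skipped: disjoint from both
    a <- sum(genes_specific %in% mem)
    b <- length(genes_specific) - a
    c <- sum(genes_no_de %in% mem)
    d <- length(genes_no_de) - c
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    data.frame(set = nm, odds_ratio = unname(ft$estimate), p = ft$p.value,
               n_in_set = length(mem), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$q <- stats::p.adjust(res$p, "BH")
  res
}
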