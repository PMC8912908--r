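## Heart-failure stage: joint PCA on the RBP panel, PC-space distances with
## paired tests, the RBP effect-size location test, and the fetal-reversion
## isoform statistic.

#' Joint PCA on the RBP expression panel
#'
#' Per RBP, log2(TPM + 1) is z-scored across all samples (healthy and heart
#' failure jointly); PCA is computed by SVD. Constant RBPs are dropped with
#' a warning; each component's sign is fixed by making the largest-|loading|
#' RBP positive, so results are fully deterministic.
#'
#' @param tpm \linkS4class{FeatureMatrix} (kind "tpm") restricted to, or
#'   containing, the RBP panel.
#' @param rbp_genes character vector of RBP gene ids (>= 10 present
#'   required).
#' @return list: \code{scores} (sample x PC), \code{loadings} (RBP x PC),
#'   \code{var_explained} (fraction per PC), \code{dropped}.
#' @export
jointRbpPca <- function(tpm, rbp_genes) {
  v <- as.matrix(tpm)
  present <- intersect(rbp_genes, rownames(v))
  if (length(present) < 10)
    stop("need >= 10 RBPs present in the matrix; found ", length(present))
  x <- log2(v[present, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  dropped <- present[sds == 0]
  if (length(dropped))
    warning("constant RBP(s) dropped: ", paste(dropped, collapse = ", "))
  x <- x[sds > 0, , drop = FALSE]
  z <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  sv <- svd(t(z))                               # samples x RBPs
  k <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, k, k)
  loadings <- sv$v
  for (j in seq_len(k)) {                       # deterministic sign
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(colnames(z), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(rownames(z), paste0("PC", seq_len(k)))
  list(scores = scores, loadings = loadings,
       var_explained = sv$d^2 / sum(sv$d^2), dropped = dropped)
}

#' Mean PC-space distances of heart-failure samples to healthy groups
#'
#' For each paired pre/post-LVAD heart-failure sample, the mean Euclidean
#' distance in the top-K PC space to every sample of each healthy group,
#' with a paired t-test of the pre-vs-post difference per target group.
#' Unpaired heart-failure samples are excluded with a warning.
#'
#' @param pcs sample x PC score matrix (\code{\link{jointRbpPca}} scores).
#' @param samples sample table (tissue and subject_id columns; HF_pre /
#'   HF_post pairs match by subject).
#' @param groups healthy tissue labels to measure against.
#' @param K number of leading PCs.
#' @return list: \code{distances} (long data.frame subject x phase x group),
#'   \code{paired_tests} (per group: mean pre-post difference, t, p).
#' @export
groupDistances <- function(pcs, samples,
                           groups = c("iPSC-CVPC", "adult_heart"), K = 10) {
  K <- min(K, ncol(pcs))
  sc <- pcs[, seq_len(K), drop = FALSE]
  pre <- samples[samples$tissue == "HF_pre", ]
  post <- samples[samples$tissue == "HF_post", ]
  subj <- intersect(pre$subject_id, post$subject_id)
  lone <- setdiff(union(pre$subject_id, post$subject_id), subj)
  if (length(lone))
    warning("unpaired HF sample(s) excluded: ", paste(lone, collapse = ", "))
  meanDist <- function(sampleId, group) {
    gs <- samples$sample_id[samples$tissue == group]
    d <- sqrt(colSums((t(sc[gs, , drop = FALSE]) - sc[sampleId, ])^2))
    mean(d)
  }
  rows <- list(); tests <- list()
  for (g in groups) {
    dpre <- vapply(subj, function(s)
      meanDist(pre$sample_id[pre$subject_id == s], g), numeric(1))
    dpost <- vapply(subj, function(s)
      meanDist(post$sample_id[post$subject_id == s], g), numeric(1))
    rows[[g]] <- data.frame(subject_id = subj, group = g, pre = dpre,
                            post = dpost, diff = dpre - dpost,
                            row.names = NULL, stringsAsFactors = FALSE)
    if (stats::sd(dpre - dpost) == 0) {
      ## degenerate pairs: constant difference carries no within-pair
      ## variance; report p = 1 for zero shift, p = 0 otherwise
      tests[[g]] <- data.frame(group = g, mean_diff = mean(dpre - dpost),
                               t = NA_real_,
                               p = if (all(dpre == dpost)) 1 else 0,
                               stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(dpre, dpost, paired = TRUE)
      tests[[g]] <- data.frame(group = g, mean_diff = mean(dpre - dpost),
                               t = unname(tt$statistic), p = tt$p.value,
                               stringsAsFactors = FALSE)
    }
  }
  list(distances = do.call(rbind, rows),
       paired_tests = do.call(rbind, tests))
}

#' One-sample location test of RBP effect sizes
#'
#' Two-sided one-sample t-test of the per-RBP DE effect sizes against zero:
#' is the RBP panel as a whole shifted (e.g. overexpressed in the fetal-like
#' state)? With all effects identical (sd = 0) the test degenerates; the
#' result is flagged and p is reported as 0 for a nonzero common value, 1
#' otherwise.
#'
#' @param effects numeric vector of per-RBP effect sizes (>= 3 required).
#' @return list: mean, t, p, n, degenerate.
#' @export
rbpEffectSizeLocationTest <- function(effects) {
  effects <- effects[is.finite(effects)]
  if (length(effects) < 3) stop("need >= 3 RBP effect sizes")
  if (stats::sd(effects) == 0) {
    return(list(mean = mean(effects), t = NA_real_,
                p = if (mean(effects) == 0) 1 else 0,
                n = length(effects), degenerate = TRUE))
  }
  tt <- stats::t.test(effects, mu = 0)
  list(mean = mean(effects), t = unname(tt$statistic), p = tt$p.value,
       n = length(effects), degenerate = FALSE)
}

#' Fetal-reversion statistic for heart-failure isoforms
#'
#' Over the isoform universe shared by the two DE runs, builds the 2x2
#' table: A = isoforms DE in heart failure vs healthy heart AND DE in the
#' fetal-like vs healthy-heart comparison with the same effect sign
#' ("reverting with the fetal trend"); B = HF-DE but not A; C = not HF-DE
#' but fetal-DE with the same effect sign; D = the remainder. The
#' same-trend condition applies to both rows, so under independence of the
#' two comparisons the odds ratio is 1. Fisher's exact test gives the
#' conditional-MLE odds ratio; the Pearson correlation of the two effect
#' vectors over the universe is also reported.
#'
#' @param de_hf DE table for heart failure vs healthy heart (feature_id,
#'   effect, p_adj).
#' @param de_fetal DE table for fetal-like vs healthy heart.
#' @param alpha adjusted-p threshold defining DE.
#' @return list: table (2x2), counts (A, B, C, D), odds_ratio, conf_int, p,
#'   r, n_universe, n_hf_de, n_same_trend.
#' @export
reversionStatistic <- function(de_hf, de_fetal, alpha = 0.05) {
  uni <- intersect(de_hf$feature_id, de_fetal$feature_id)
  if (!length(uni)) stop("empty isoform universe")
  hf <- de_hf[match(uni, de_hf$feature_id), ]
  fe <- de_fetal[match(uni, de_fetal$feature_id), ]
  ## features without a valid test in either run (e.g. constant usage)
  ## cannot be classified and leave the universe
  ok <- is.finite(hf$p_adj) & is.finite(fe$p_adj) &
    is.finite(hf$effect) & is.finite(fe$effect)
  uni <- uni[ok]; hf <- hf[ok, ]; fe <- fe[ok, ]
  if (!length(uni)) stop("empty isoform universe")
  hfDE <- hf$p_adj < alpha
  feDE <- fe$p_adj < alpha
  same <- sign(hf$effect) == sign(fe$effect)
  A <- sum(hfDE & feDE & same)
  B <- sum(hfDE) - A
  C <- sum(!hfDE & feDE & same)
  D <- length(uni) - A - B - C
  tab <- matrix(c(A, B, C, D), 2, byrow = TRUE,
                dimnames = list(c("HF_DE", "not_HF_DE"),
                                c("fetal_same_trend", "other")))
  ft <- stats::fisher.test(tab)
  list(table = tab, counts = c(A = A, B = B, C = C, D = D),
       odds_ratio = unname(ft$estimate), conf_int = unname(ft$conf.int),
       p = ft$p.value, r = stats::cor(hf$effect, fe$effect),
       n_universe = length(uni), n_hf_de = sum(hfDE), n_same_trend = A)
}
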