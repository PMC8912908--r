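## Cell-type deconvolution: marker selection from labeled single-cell
## counts, signature-matrix construction, mixture-proportion estimation
## (nu-SVR over a nu grid with negative-coefficient truncation, or NNLS),
## and proportion-expression association.

#' Find cell-type marker genes from labeled single-cell counts
#'
#' One-vs-rest Wilcoxon rank-sum tests on log-normalized counts (counts
#' scaled to 10,000 per cell, log1p). A gene is a marker of a type when its
#' shift is positive, it is detected in at least \code{min_pct} of in-type
#' cells, its log2 fold change is at least \code{logfc_threshold}, and its
#' Bonferroni-adjusted p-value is below \code{alpha}. Types with fewer than
#' two cells are excluded with a warning.
#'
#' @param sc_counts gene x cell count matrix.
#' @param labels cell-type label per cell (named or in column order).
#' @param min_pct minimum detection fraction among in-type cells.
#' @param logfc_threshold minimum log2 fold change (log-normalized scale).
#' @param alpha Bonferroni-adjusted p threshold.
#' @return data.frame: gene_id, cell_type, pct_in, pct_out, log2fc, p,
#'   p_adj.
#' @export
findMarkers <- function(sc_counts, labels, min_pct = 0.2,
                        logfc_threshold = 0.1, alpha = 0.1) {
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(sc_counts))
  depth <- colSums(sc_counts)
  logn <- log1p(t(t(sc_counts) / depth) * 1e4)
  types <- names(which(table(labels) >= 2))
  drop <- setdiff(unique(labels), types)
  if (length(drop))
    warning("type(s) with < 2 cells excluded: ", paste(drop, collapse = ", "))
  rows <- lapply(types, function(tt) {
    inC <- labels == tt
    lin <- logn[, inC, drop = FALSE]
    lout <- logn[, !inC, drop = FALSE]
    pctIn <- rowMeans(lin > 0)
    pctOut <- rowMeans(lout > 0)
    l2fc <- (rowMeans(lin) - rowMeans(lout)) / log(2)
    cand <- which(l2fc >= logfc_threshold & pctIn >= min_pct)
    if (!length(cand)) return(NULL)
    p <- vapply(cand, function(g)
      stats::wilcox.test(lin[g, ], lout[g, ],
                         alternative = "greater")$p.value, numeric(1))
    data.frame(gene_id = rownames(sc_counts)[cand], cell_type = tt,
               pct_in = pctIn[cand], pct_out = pctOut[cand],
               log2fc = l2fc[cand], p = p, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$p_adj <- pmin(res$p * nrow(sc_counts), 1)
  res[res$p_adj < alpha, , drop = FALSE]
}

#' Build a signature matrix from markers
#'
#' Per marker gene per cell type, the arithmetic mean of depth-normalized
#' (counts per 10,000, un-logged) expression. Duplicated marker rows collapse
#' to one.
#'
#' @param sc_counts gene x cell count matrix.
#' @param labels cell-type label per cell.
#' @param markers marker table from \code{\link{findMarkers}} (or a character
#'   vector of gene ids).
#' @return marker gene x cell type matrix with the marker table attached as
#'   attribute \code{provenance}.
#' @export
buildSignature <- function(sc_counts, labels, markers) {
  genes <- unique(if (is.data.frame(markers)) markers$gene_id else markers)
  if (!length(genes)) stop("markers must be nonempty")
  absent <- setdiff(genes, rownames(sc_counts))
  if (length(absent))
    stop("marker(s) absent from counts: ",
         paste(utils::head(absent, 5), collapse = ", "))
  labels <- as.character(labels)
  norm <- t(t(sc_counts) / colSums(sc_counts)) * 1e4
  types <- sort(unique(labels))
  sig <- vapply(types, function(tt)
    rowMeans(norm[genes, labels == tt, drop = FALSE]), numeric(length(genes)))
  rownames(sig) <- genes
  attr(sig, "provenance") <- if (is.data.frame(markers)) markers else NULL
  sig
}

.jointZ <- function(sig, b) {
  ## z-score signature and mixture jointly against the pooled values; this
  ## keeps the linear mixture relationship exact when the weights sum to 1
  ## (no quantile mapping is ever applied)
  pool <- c(as.numeric(sig), as.numeric(b))
  m <- mean(pool); s <- stats::sd(pool)
  if (s == 0) s <- 1
  list(sig = (sig - m) / s, b = (b - m) / s)
}

#' Estimate cell-type proportions from bulk expression
#'
#' CIBERSORT-style core: per sample, marker rows of the bulk profile and the
#' signature are jointly z-scored per gene (no quantile mapping); support
#' vector regression with linear kernel is run over nu in {0.25, 0.5, 0.75}
#' and the fit with the smallest RMSE against the mixture is kept (method
#' "nusvr"), or nonnegative least squares is used directly (method "nnls").
#' Negative coefficients are truncated to zero and the remainder is
#' renormalized to the unit simplex.
#'
#' @param bulk \linkS4class{FeatureMatrix} (kind "tpm") containing the marker
#'   genes.
#' @param sig signature matrix from \code{\link{buildSignature}}.
#' @param method \code{"nusvr"} or \code{"nnls"}.
#' @return list with \code{proportions} (sample x cell-type matrix, rows on
#'   the simplex) and \code{diagnostics} (per-sample RMSE and chosen nu).
#' @export
estimateProportions <- function(bulk, sig, method = c("nusvr", "nnls")) {
  method <- match.arg(method)
  v <- as.matrix(bulk)
  miss <- setdiff(rownames(sig), rownames(v))
  if (length(miss))
    stop("marker(s) missing from bulk matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  v <- v[rownames(sig), , drop = FALSE]
  K <- ncol(sig)
  props <- matrix(0, ncol(v), K, dimnames = list(colnames(v), colnames(sig)))
  rmse <- numeric(ncol(v)); nuSel <- rep(NA_real_, ncol(v))
  for (s in seq_len(ncol(v))) {
    b <- v[, s]
    if (all(b == 0)) stop("all-zero mixture column: ", colnames(v)[s])
    ## scale calibration: bring the mixture onto the signature scale so the
    ## per-gene joint z-score preserves the linear mixture relationship
    ## (mixture and signature units generally differ, e.g. TPM vs CP10K)
    w0 <- pracma::lsqnonneg(sig, b)$x
    if (sum(w0) > 0) b <- b / sum(w0)
    z <- .jointZ(sig, b)
    if (method == "nnls") {
      w <- pracma::lsqnonneg(z$sig, z$b)$x
    } else {
      bestRmse <- Inf; w <- rep(0, K)
      for (nu in c(0.25, 0.5, 0.75)) {
        fit <- e1071::svm(z$sig, z$b, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
        wi <- as.numeric(t(fit$coefs) %*% fit$SV)
        wi[wi < 0] <- 0
        pred <- z$sig %*% wi
        r <- sqrt(mean((pred - z$b)^2))
        if (r < bestRmse) { bestRmse <- r; w <- wi; nuSel[s] <- nu }
      }
    }
    w[w < 0] <- 0
    if (sum(w) == 0) w <- rep(1 / K, K)
    props[s, ] <- w / sum(w)
    rmse[s] <- sqrt(mean((z$sig %*% props[s, ] - z$b)^2))
  }
  list(proportions = props,
       diagnostics = data.frame(sample_id = colnames(v), rmse = rmse,
                                nu = nuSel, method = method,
                                stringsAsFactors = FALSE))
}

#' Associate feature expression with cell-type proportions
#'
#' Per feature per cell type, OLS of the normalized phenotype on that single
#' proportion plus the four technical covariates; Bonferroni correction is
#' applied across features within each cell type. Constant proportion
#' columns are skipped with a warning.
#'
#' @param norm normalized \linkS4class{FeatureMatrix}.
#' @param samples sample table covering the matrix columns.
#' @param proportions sample x cell-type matrix.
#' @return data.frame keyed by cell_type: feature_id, effect, se, p, p_adj.
#' @export
proportionAssociation <- function(norm, samples, proportions) {
  stopifnot(is(norm, "FeatureMatrix"))
  Y <- as.matrix(norm)[, samples$sample_id, drop = FALSE]
  P <- proportions[samples$sample_id, , drop = FALSE]
  C <- covariateMatrix(samples)
  rows <- lapply(colnames(P), function(ct) {
    e <- P[, ct]
    if (stats::sd(e) == 0) {
      warning("constant proportion column skipped: ", ct)
      return(NULL)
    }
    X <- cbind(intercept = 1, proportion = e, C)
    res <- .olsAcross(Y, X, "proportion")
    res$p_adj <- pmin(res$p * nrow(res), 1)
    res$cell_type <- ct
    res
  })
  do.call(rbind, rows)
}
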