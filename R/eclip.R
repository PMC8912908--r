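## eCLIP peak-overlap enrichment: are genes with tissue-specific isoforms
## more likely to overlap in-vivo RBP binding sites? Tested as a sweep over
## 13 log2-ratio cutoffs against genes with no DE isoform at all.

#' Genes whose bodies overlap eCLIP peaks
#'
#' A gene is included iff its body shares at least 1 bp with at least one
#' peak (strand-blind).
#'
#' @param gene_bodies named GRanges (see \code{\link{geneBodyIntervals}}).
#' @param peaks a \linkS4class{PeakSet}.
#' @return character vector of gene ids.
#' @export
genesOverlappingPeaks <- function(gene_bodies, peaks) {
  if (!length(peakRanges(peaks))) return(character(0))
  hit <- countOverlaps(gene_bodies, peakRanges(peaks),
                       ignore.strand = TRUE) > 0
  names(gene_bodies)[hit]
}

#' Threshold sweep of peak-overlap enrichment
#'
#' At each cutoff tau of the grid (default 0..6 by 0.5 -- 13 thresholds),
#' the "specific" genes of a direction are the genes owning at least one
#' isoform with p_adj < alpha and log2_ratio beyond tau (> tau for
#' direction 1, < -tau for direction 2). The background is the genes none of
#' whose isoforms are DE at all; genes with DE isoforms failing the cutoff
#' belong to neither side. Genes qualifying for both directions at a cutoff
#' are assigned to the direction of their largest |log2_ratio| isoform. Per
#' eCLIP experiment and direction, a Fisher exact test contrasts
#' peak-overlap fractions of specific vs background genes; a mean curve
#' (mean log2 OR across experiments) is also returned.
#'
#' @param iso_de isoform-level DE table with columns feature_id, p_adj,
#'   log2_ratio.
#' @param iso_gene named character: isoform id -> gene id.
#' @param gene_bodies named GRanges of gene bodies.
#' @param peaksets list of \linkS4class{PeakSet} objects.
#' @param grid numeric cutoff grid.
#' @param alpha adjusted-p threshold defining DE.
#' @return list with \code{curves} (long data.frame: experiment, rbp,
#'   direction, tau, n_specific, n_background, odds_ratio, log2_or, p) and
#'   \code{mean_curve} (direction x tau mean log2 OR).
#' @export
thresholdSweep <- function(iso_de, iso_gene, gene_bodies, peaksets,
                           grid = seq(0, 6, by = 0.5), alpha = 0.05) {
  stopifnot(length(grid) > 0)
  gene <- unname(iso_gene[iso_de$feature_id])
  de <- iso_de$p_adj < alpha
  background <- setdiff(names(gene_bodies)[names(gene_bodies) %in% gene],
                        unique(gene[de]))
  if (!length(background)) stop("background gene set is empty")
  overlapSets <- lapply(peaksets, function(ps)
    genesOverlappingPeaks(gene_bodies, ps))
  ## per gene: extreme log2 ratios among DE isoforms
  deTab <- data.frame(gene = gene[de], lr = iso_de$log2_ratio[de],
                      stringsAsFactors = FALSE)
  maxUp <- tapply(deTab$lr, deTab$gene, max)
  maxDn <- tapply(deTab$lr, deTab$gene, min)
  ## a gene follows the sign of its largest-|log2 ratio| DE isoform
  extreme <- ifelse(abs(maxUp) >= abs(maxDn), maxUp, maxDn)
  dirOf <- ifelse(extreme > 0, 1L, 2L)                 # tie -> direction 1
  rows <- list()
  for (tau in grid) {
    up <- names(maxUp)[maxUp > tau & dirOf == 1L]
    dn <- names(maxDn)[maxDn < -tau & dirOf == 2L]
    for (dir in 1:2) {
      specific <- if (dir == 1L) up else dn
      for (e in seq_along(peaksets)) {
        ps <- peaksets[[e]]
        if (!length(specific)) {
          rows[[length(rows) + 1L]] <- data.frame(
            experiment = ps@experiment_id, rbp = ps@rbp_name,
            direction = dir, tau = tau, n_specific = 0L,
            n_background = length(background), odds_ratio = NA_real_,
            log2_or = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
          next
        }
        ov <- overlapSets[[e]]
        a <- sum(specific %in% ov); b <- length(specific) - a
        c <- sum(background %in% ov); d <- length(background) - c
        ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
        rows[[length(rows) + 1L]] <- data.frame(
          experiment = ps@experiment_id, rbp = ps@rbp_name, direction = dir,
          tau = tau, n_specific = length(specific),
          n_background = length(background),
          odds_ratio = unname(ft$estimate),
          log2_or = log2(unname(ft$estimate)), p = ft$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  curves <- do.call(rbind, rows)
  mean_curve <- stats::aggregate(log2_or ~ direction + tau, curves, mean,
                                 na.action = stats::na.omit)
  list(curves = curves, mean_curve = mean_curve)
}
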