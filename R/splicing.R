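## Tissue-specific exon derivation and the exon-sequence analyses:
## protein-domain overlap, splice-site positional nucleotide tests,
## polypyrimidine profiling, and PWM motif-window enrichment.

#' Construct an exon-set pair
#'
#' Two disjoint exon-id sets labeled by the tissues they are specific to.
#'
#' @param set1,set2 character vectors of exon ids.
#' @param tissue1,tissue2 tissue labels.
#' @param label comparison label.
#' @return list of class \code{ExonSetPair}.
#' @export
exonSetPair <- function(set1, set2, tissue1, tissue2,
                        label = paste(tissue1, "vs", tissue2)) {
  set1 <- unique(set1); set2 <- unique(set2)
  if (length(intersect(set1, set2)))
    stop("exon sets must be disjoint")
  structure(list(set1 = set1, set2 = set2, tissue1 = tissue1,
                 tissue2 = tissue2, label = label), class = "ExonSetPair")
}

#' @export
print.ExonSetPair <- function(x, ...) {
  cat(sprintf("ExonSetPair '%s': %d %s exons vs %d %s exons\n", x$label,
              length(x$set1), x$tissue1, length(x$set2), x$tissue2))
  invisible(x)
}

#' Derive tissue-specific exon sets from specific isoforms
#'
#' Only genes carrying at least one tissue1-specific AND at least one
#' tissue2-specific isoform are used. Within those genes, the tissue1 set is
#' the exon ids of tissue1-specific isoforms minus the exon ids of
#' tissue2-specific isoforms (shared exon ids mark identical coordinates),
#' and symmetrically for tissue2.
#'
#' @param specific1,specific2 transcript ids of tissue1- / tissue2-specific
#'   isoforms.
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @param tissue1,tissue2 tissue labels for the output.
#' @return an \code{\link{exonSetPair}}.
#' @export
deriveSpecificExons <- function(specific1, specific2, ann,
                                tissue1 = "tissue1", tissue2 = "tissue2") {
  txg <- txToGene(ann)
  g1 <- unique(txg[specific1]); g2 <- unique(txg[specific2])
  both <- intersect(g1, g2)
  s1 <- specific1[txg[specific1] %in% both]
  s2 <- specific2[txg[specific2] %in% both]
  ex1 <- unique(unlist(annTranscripts(ann)[s1], use.names = FALSE))
  ex2 <- unique(unlist(annTranscripts(ann)[s2], use.names = FALSE))
  exonSetPair(setdiff(ex1, ex2), setdiff(ex2, ex1), tissue1, tissue2)
}

#' Protein-domain overlap enrichment between exon sets
#'
#' An exon overlaps iff it shares at least 1 bp with any domain interval
#' (strand-blind). A 2x2 Fisher exact test contrasts the overlap fractions
#' of the two sets.
#'
#' @param pair an \code{\link{exonSetPair}}.
#' @param exons named GRanges resolving the pair's exon ids.
#' @param domains GRanges of protein-domain intervals.
#' @return list: per-set overlap counts/flags, odds_ratio, conf_int, p;
#'   \code{skipped = TRUE} when either set is empty.
#' @export
domainOverlapTest <- function(pair, exons, domains) {
  if (!length(pair$set1) || !length(pair$set2))
    return(list(skipped = TRUE, reason = "empty exon set"))
  ov <- function(ids) countOverlaps(exons[ids], domains,
                                    ignore.strand = TRUE) > 0
  o1 <- ov(pair$set1); o2 <- ov(pair$set2)
  tab <- matrix(c(sum(o1), sum(!o1), sum(o2), sum(!o2)), 2, byrow = TRUE)
  ft <- stats::fisher.test(tab)
  list(skipped = FALSE, table = tab, overlap1 = o1, overlap2 = o2,
       odds_ratio = unname(ft$estimate), conf_int = unname(ft$conf.int),
       p = ft$p.value)
}

## sequence windows flanking an exon, in transcription orientation
.exonFlank <- function(exon, genome, side, len) {
  chrom <- as.character(seqnames(exon))
  str <- as.character(strand(exon))
  anchor <- if (side == "acceptor") {
    if (str == "+") start(exon) - 1L else end(exon)
  } else {
    if (str == "+") end(exon) else start(exon) - 1L
  }
  suppressWarnings(
    extractWindow(genome, chrom, anchor, len,
                  side = if (side == "acceptor") "up" else "down",
                  strand = str))
}

## vectorized flank windows for many exons; returns oriented sequences plus
## the number of positions missing at the 5' end of each window (chromosome
## edge truncation)
.flankWindows <- function(ids, exons, genome, side, len) {
  if (!length(ids))
    return(list(seq = character(0), lead = integer(0), ids = character(0)))
  i <- match(ids, names(exons))
  chr <- as.character(seqnames(exons))[i]
  st <- start(exons)[i]; en <- end(exons)[i]
  plus <- as.character(strand(exons))[i] == "+"
  present <- chr %in% names(genome)
  if (!all(present))
    warning("exon(s) on missing chromosome skipped: ",
            paste(utils::head(ids[!present], 3), collapse = ", "))
  ids <- ids[present]; chr <- chr[present]; st <- st[present]
  en <- en[present]; plus <- plus[present]
  clen <- stats::setNames(Biostrings::width(genome), names(genome))[chr]
  ## genomic window: left of the exon for (acceptor & plus) | (donor & minus)
  left <- (side == "acceptor") == plus
  ws <- ifelse(left, st - len, en + 1L)
  we <- ifelse(left, st - 1L, en + len)
  wsC <- pmax(ws, 1L); weC <- pmin(we, clen)
  lostL <- wsC - ws; lostR <- we - weC
  seqs <- character(length(ids))
  for (ch in unique(chr)) {
    k <- chr == ch
    seqs[k] <- substring(as.character(genome[[ch]]), wsC[k], weC[k])
  }
  minus <- !plus
  if (any(minus))
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  list(seq = toupper(seqs), lead = ifelse(plus, lostL, lostR), ids = ids)
}

## 4 x len positional count matrix from oriented windows
.positionCounts <- function(win, len, colNames) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(0L, 4, len, dimnames = list(bases, as.character(colNames)))
  if (!length(win$seq)) return(out)
  pad <- function(s, m) paste0(strrep("N", m),
                               s, strrep("N", len - m - nchar(s)))
  padded <- mapply(pad, win$seq, win$lead, USE.NAMES = FALSE)
  mat <- matrix(unlist(strsplit(padded, ""), use.names = FALSE), nrow = len)
  for (b in bases) out[b, ] <- rowSums(matrix(mat == b, nrow = len))
  out
}

#' Positional nucleotide profiles around splice sites
#'
#' For each exon of each set, extracts the acceptor window (\code{up} nt
#' upstream of the exon start, transcription orientation; positions -up..-1)
#' and the donor window (\code{down} nt downstream of the exon end;
#' positions +1..+down) and counts A/C/G/T per position. Windows truncated
#' at a chromosome edge contribute only their covered positions; exons on
#' chromosomes missing from the genome are skipped with a warning.
#'
#' @param pair an \code{\link{exonSetPair}}.
#' @param exons named GRanges resolving the exon ids.
#' @param genome named DNAStringSet.
#' @param up,down window lengths.
#' @return list of class \code{SpliceSiteProfiles}: for each set, 4 x up
#'   (acceptor) and 4 x down (donor) count matrices; column names are signed
#'   positions.
#' @export
spliceProfiles <- function(pair, exons, genome, up = 100, down = 100) {
  profileSet <- function(ids) {
    list(acceptor = .positionCounts(
           .flankWindows(ids, exons, genome, "acceptor", up), up, -up:-1),
         donor = .positionCounts(
           .flankWindows(ids, exons, genome, "donor", down), down, 1:down))
  }
  structure(list(set1 = profileSet(pair$set1), set2 = profileSet(pair$set2),
                 pair = pair), class = "SpliceSiteProfiles")
}

#' Per-position Fisher tests of nucleotide composition
#'
#' At every position and nucleotide, a 2x2 Fisher exact test contrasts
#' is-this-nucleotide counts between the two sets. Benjamini-Hochberg
#' correction is applied across all positions and nucleotides within each
#' side. All four nucleotide tests are reported; the most common nucleotide
#' per position is flagged for display. Zero-margin tables get OR = NA and
#' p = 1.
#'
#' @param profiles a \code{SpliceSiteProfiles} object.
#' @param sides which sides to test.
#' @return data.frame: side, position, nucleotide, count1, n1, count2, n2,
#'   odds_ratio, conf_lo, conf_hi, p, p_adj, most_common.
#' @export
positionalTests <- function(profiles, sides = c("acceptor", "donor")) {
  out <- lapply(sides, function(sd) {
    m1 <- profiles$set1[[sd]]; m2 <- profiles$set2[[sd]]
    n1 <- colSums(m1); n2 <- colSums(m2)
    rows <- lapply(colnames(m1), function(pos) {
      if (n1[pos] == 0 || n2[pos] == 0) return(NULL)
      mc <- rownames(m1)[which.max(m1[, pos] + m2[, pos])]
      do.call(rbind, lapply(rownames(m1), function(nt) {
        a <- m1[nt, pos]; b <- n1[pos] - a
        c <- m2[nt, pos]; d <- n2[pos] - c
        if ((a + c) == 0 || (b + d) == 0) {
          or <- NA_real_; ci <- c(NA_real_, NA_real_); p <- 1
        } else {
          ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
          or <- unname(ft$estimate); ci <- ft$conf.int; p <- ft$p.value
        }
        data.frame(side = sd, position = as.integer(pos), nucleotide = nt,
                   count1 = a, n1 = unname(n1[pos]), count2 = c,
                   n2 = unname(n2[pos]), odds_ratio = or, conf_lo = ci[1],
                   conf_hi = ci[2], p = p, most_common = nt == mc,
                   stringsAsFactors = FALSE)
      }))
    })
    res <- do.call(rbind, rows)
    if (!is.null(res)) res$p_adj <- stats::p.adjust(res$p, "BH")
    res
  })
  do.call(rbind, out)
}

#' Polypyrimidine-tract profile upstream of the splice acceptor
#'
#' Per acceptor position, the thymine and pyrimidine (C+T) fractions of each
#' set, with a thymine-vs-not Fisher test per position (BH-corrected across
#' the positions). The canonical acceptor context carries a T-rich tract of
#' 15-20 nt shortly upstream of the AG.
#'
#' @param profiles a \code{SpliceSiteProfiles} object.
#' @return list: \code{table} (per-position fractions + thymine test),
#'   \code{n_sig_set1}, \code{n_sig_set2} (significant positions where
#'   thymine is enriched in set1 / set2).
#' @export
polypyrimidineProfile <- function(profiles) {
  m1 <- profiles$set1$acceptor; m2 <- profiles$set2$acceptor
  n1 <- colSums(m1); n2 <- colSums(m2)
  pos <- colnames(m1)
  rows <- lapply(pos, function(p) {
    if (n1[p] == 0 || n2[p] == 0) return(NULL)
    a <- m1["T", p]; c <- m2["T", p]
    ft <- stats::fisher.test(matrix(c(a, n1[p] - a, c, n2[p] - c), 2,
                                    byrow = TRUE))
    data.frame(position = as.integer(p),
               t_frac1 = a / n1[p], t_frac2 = c / n2[p],
               py_frac1 = (m1["C", p] + a) / n1[p],
               py_frac2 = (m2["C", p] + c) / n2[p],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adj <- stats::p.adjust(tab$p, "BH")
  sig <- tab$p_adj < 0.05
  list(table = tab,
       n_sig_set1 = sum(sig & tab$t_frac1 > tab$t_frac2, na.rm = TRUE),
       n_sig_set2 = sum(sig & tab$t_frac2 > tab$t_frac1, na.rm = TRUE))
}

## max log-odds PWM score over sense-strand offsets of a window
.pwmMaxScore <- function(window, logOdds) {
  L <- ncol(logOdds)
  idx <- match(strsplit(window, "")[[1]], c("A", "C", "G", "T"))
  n <- length(idx)
  if (n < L) return(-Inf)
  best <- -Inf
  for (o in 0:(n - L)) {
    sub <- idx[(o + 1):(o + L)]
    if (anyNA(sub)) next
    s <- sum(logOdds[cbind(sub, seq_len(L))])
    if (s > best) best <- s
  }
  best
}

#' Motif enrichment in acceptor-side windows
#'
#' Builds the 100-bp window upstream of each exon (acceptor side,
#' transcription orientation), excluding exons that are the first exon of
#' any isoform. A window "contains" a motif when its maximum log-odds score
#' (PWM against a uniform background, sense strand only -- the motifs are
#' RNA-binding) reaches \code{score_frac} of the motif's maximum attainable
#' score. Per motif, one-sided Fisher tests are run in both directions;
#' after BH correction per direction across motifs, the direction with the
#' smaller q is kept and the log2 ratio of containment proportions is
#' signed positive for set1 enrichment.
#'
#' @param pair an \code{\link{exonSetPair}}.
#' @param ann a \linkS4class{TranscriptAnnotation} (for first-exon removal).
#' @param genome named DNAStringSet.
#' @param pwms list of \linkS4class{PWMotif} objects.
#' @param window window length upstream of the exon start.
#' @param score_frac containment threshold as a fraction of the maximum
#'   attainable log-odds score.
#' @return data.frame: motif_id, rbp_name, contain1, n1, contain2, n2,
#'   log2_ratio, favored, p, q.
#' @export
motifWindowEnrichment <- function(pair, ann, genome, pwms, window = 100,
                                  score_frac = 0.8) {
  firstExons <- unique(vapply(annTranscripts(ann), `[`, character(1), 1))
  s1 <- setdiff(pair$set1, firstExons)
  s2 <- setdiff(pair$set2, firstExons)
  exons <- annExons(ann)
  w1 <- .flankWindows(s1, exons, genome, "acceptor", window)$seq
  w2 <- .flankWindows(s2, exons, genome, "acceptor", window)$seq
  rows <- lapply(pwms, function(pw) {
    m <- pwmMatrix(pw)
    if (ncol(m) > window) {
      warning("PWM longer than window skipped: ", pw@motif_id)
      return(NULL)
    }
    lo <- log2(pmax(m, 0.01) / 0.25)     # pseudocount guards zero columns
    maxScore <- sum(apply(lo, 2, max))
    thr <- score_frac * maxScore
    c1 <- sum(vapply(w1, .pwmMaxScore, numeric(1), logOdds = lo) >= thr)
    c2 <- sum(vapply(w2, .pwmMaxScore, numeric(1), logOdds = lo) >= thr)
    n1 <- length(w1); n2 <- length(w2)
    tab <- matrix(c(c1, n1 - c1, c2, n2 - c2), 2, byrow = TRUE)
    data.frame(motif_id = pw@motif_id, rbp_name = pw@rbp_name,
               contain1 = c1, n1 = n1, contain2 = c2, n2 = n2,
               log2_ratio = log2(((c1 + 0.5) / (n1 + 1)) /
                                 ((c2 + 0.5) / (n2 + 1))),
               p_set1 = stats::fisher.test(tab, alternative = "greater")$p.value,
               p_set2 = stats::fisher.test(tab, alternative = "less")$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  q1 <- stats::p.adjust(res$p_set1, "BH")
  q2 <- stats::p.adjust(res$p_set2, "BH")
  keep1 <- q1 <= q2
  res$favored <- ifelse(keep1, pair$tissue1, pair$tissue2)
  res$p <- ifelse(keep1, res$p_set1, res$p_set2)
  res$q <- ifelse(keep1, q1, q2)
  res$p_set1 <- res$p_set2 <- NULL
  res
}
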