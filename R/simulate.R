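## Synthetic-cohort generator. Emits bulk gene/isoform TPM with planted
## stage-specific effects and isoform switches, cell-type mixture structure,
## a consistent annotation + genome, eCLIP-like peaks, motifs, gene sets,
## protein domains and a labeled single-cell fixture -- together with the
## ground truth needed to measure recovery downstream.

CELL_TYPES <- c("cardiac_muscle", "cardiac_neuron", "endothelial",
                "fibroblast", "immune", "smooth_muscle")

.defaultDirichlet <- function() {
  ## concentrations ~ 50 x mean proportion; fetal-like tissue carries almost
  ## no fibroblast/immune mass, arteria is smooth-muscle dominated
  list(
    "iPSC-CVPC"     = c(31,   2.5,  10,   0.05, 0.15,  6.3),
    "adult_heart"   = c(27.5, 2.5,  7.5,  5,    2.5,   5),
    "adult_arteria" = c(2.5,  1.5,  7.5,  7.5,  4,    27),
    "HF_pre"        = c(27.5, 2.5,  7.5,  5,    2.5,   5),
    "HF_post"       = c(27.5, 2.5,  7.5,  5,    2.5,   5))
}

#' Configuration for the synthetic cohort
#'
#' Defaults encode the study conditions the pipeline is designed around:
#' three healthy tissue groups (40 fetal-like iPSC-CVPC, 40 adult heart, 30
#' adult arteria) plus 8 paired pre/post-LVAD heart-failure samples; 2,000
#' genes, half with 2-4 isoforms; 300 stage-DE genes with |log2FC| ~
#' U(2.5, 4) concentrated in a designated 120-gene RBP panel with
#' fetal-overexpression bias; 250 switch isoform pairs with usage shift
#' U(0.3, 0.6); half of the switch pairs reverting toward the fetal usage in
#' pre-LVAD samples; multiplicative lognormal noise with sigma = 0.25 on the
#' log2 scale.
#'
#' @param n_ipsc,n_heart,n_arteria healthy samples per tissue.
#' @param n_hf_pairs paired pre/post-LVAD heart-failure subjects.
#' @param n_genes total genes.
#' @param frac_multi_isoform fraction of genes with 2-4 isoforms.
#' @param n_stage_de number of stage-DE genes (includes the RBP panel).
#' @param n_rbp size of the designated RBP gene panel.
#' @param rbp_fetal_bias probability that an RBP stage effect is fetal-up.
#' @param lfc_range range of |log2FC| for stage-DE genes.
#' @param n_switch switch isoform pairs (fetal vs adult usage shift).
#' @param n_hf_switch heart-failure-only switch pairs (disease effect
#'   independent of developmental stage; disjoint from the stage switches).
#' @param delta_range range of the planted usage shift.
#' @param hf_reversion_rho fraction of stage switch pairs that revert toward
#'   the fetal usage in pre-LVAD samples.
#' @param hf_reversion_strength fraction of the fetal-adult usage gap
#'   recovered by a reverting pre-LVAD sample.
#' @param sigma lognormal noise sd on the log2 scale.
#' @param usage_concentration Dirichlet concentration of per-sample isoform
#'   usage around its tissue mean.
#' @param markers_per_type,marker_fold cell-type marker genes per type and
#'   their within-type expression fold.
#' @param dirichlet named list of per-tissue Dirichlet concentration vectors
#'   over the six cell types (NULL = built-in defaults).
#' @param peak_prob_specific,peak_prob_background per-experiment probability
#'   that an eCLIP peak lands in a switch / non-switch gene body.
#' @param n_eclip number of eCLIP experiments.
#' @param motif_prob_specific,motif_prob_background probability that the
#'   planted motif occurs in acceptor windows of fetal- / adult-specific
#'   exons.
#' @param domain_prob_specific,domain_prob_background probability that a
#'   fetal- / adult-specific exon overlaps a protein domain.
#' @param n_gene_sets random gene sets emitted next to the RBP panel set.
#' @param sc_cells_per_type,sc_dispersion,sc_depth single-cell fixture:
#'   cells per type, NB dispersion, mean library size.
#' @param seed integer seed; a fixed seed gives bit-identical cohorts.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(n_ipsc = 40, n_heart = 40, n_arteria = 30,
                      n_hf_pairs = 8, n_genes = 2000,
                      frac_multi_isoform = 0.5, n_stage_de = 300,
                      n_rbp = 120, rbp_fetal_bias = 0.85,
                      lfc_range = c(2.5, 4), n_switch = 250,
                      n_hf_switch = 150, delta_range = c(0.3, 0.6),
                      hf_reversion_rho = 0.5, hf_reversion_strength = 0.75,
                      sigma = 0.25, usage_concentration = 150,
                      markers_per_type = 30, marker_fold = 16,
                      dirichlet = NULL, peak_prob_specific = 0.6,
                      peak_prob_background = 0.3, n_eclip = 4,
                      motif_prob_specific = 0.6,
                      motif_prob_background = 0.2,
                      domain_prob_specific = 0.6,
                      domain_prob_background = 0.35, n_gene_sets = 30,
                      sc_cells_per_type = 200, sc_dispersion = 0.5,
                      sc_depth = 5000, seed = 1) {
  cfg <- as.list(environment())
  cfg$dirichlet <- dirichlet %||% .defaultDirichlet()
  stopifnot(
    all(vapply(cfg$dirichlet, length, integer(1)) == length(CELL_TYPES)),
    all(unlist(cfg$dirichlet) > 0),
    frac_multi_isoform >= 0, frac_multi_isoform <= 1,
    rbp_fetal_bias >= 0, rbp_fetal_bias <= 1,
    hf_reversion_rho >= 0, hf_reversion_rho <= 1, sigma >= 0)
  if (n_stage_de > n_genes)
    stop("n_stage_de exceeds n_genes")
  nMulti <- round(frac_multi_isoform * n_genes)
  if (n_switch + n_hf_switch > nMulti)
    stop("n_switch + n_hf_switch exceeds the number of multi-isoform genes")
  if (n_rbp > n_stage_de)
    stop("n_rbp exceeds n_stage_de (the RBP panel is part of the DE set)")
  class(cfg) <- "SimConfig"
  cfg
}

.simSeed <- function(cfg, phase) {
  set.seed((abs(cfg$seed) + phase * 1000003L) %% 2147483647L)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = n)
  out <- t(g / rep(colSums(g), each = length(alpha)))
  colnames(out) <- names(alpha)
  out
}

#' Simulate a full synthetic cohort
#'
#' @param cfg a \code{\link{simConfig}} object.
#' @param components which fixtures to build; \code{"expression"} (sample
#'   table, proportions, gene/isoform TPM) is always built. Each component is
#'   generated from its own seed stream derived from \code{cfg$seed}, so
#'   requesting a subset does not change the values of the others.
#' @return list of class \code{SimulatedCohort} with elements
#'   \code{gene_tpm}, \code{iso_tpm} (\linkS4class{FeatureMatrix}),
#'   \code{samples} (data.frame), \code{annotation}
#'   (\linkS4class{TranscriptAnnotation}), \code{genome} (DNAStringSet),
#'   \code{peaks} (list of \linkS4class{PeakSet}), \code{motifs} (list of
#'   \linkS4class{PWMotif}), \code{gene_sets}, \code{domains} (GRanges),
#'   \code{sc_counts}, \code{sc_labels} and \code{truth} (the ground-truth
#'   record of every planted effect).
#' @export
simulateCohort <- function(cfg = simConfig(),
                           components = c("annotation", "genome", "peaks",
                                          "motifs", "genesets", "domains",
                                          "singlecell")) {
  stopifnot(inherits(cfg, "SimConfig"))
  out <- .simExpression(cfg)
  if (any(c("annotation", "genome", "peaks", "motifs", "domains")
          %in% components)) {
    out <- .simAnnotation(cfg, out)
  }
  if (any(c("genome", "motifs") %in% components))
    out <- .simGenome(cfg, out)
  if ("peaks" %in% components) out <- .simPeaks(cfg, out)
  if ("motifs" %in% components) out <- .simMotifs(cfg, out)
  if ("genesets" %in% components) out <- .simGeneSets(cfg, out)
  if ("domains" %in% components) out <- .simDomains(cfg, out)
  if ("singlecell" %in% components) out <- .simSingleCell(cfg, out)
  class(out) <- "SimulatedCohort"
  out
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat("SimulatedCohort:", nrow(as.matrix(x$gene_tpm)), "genes,",
      nrow(as.matrix(x$iso_tpm)), "isoforms,",
      ncol(as.matrix(x$gene_tpm)), "samples\n")
  invisible(x)
}

## ---- expression phase -----------------------------------------------------

.simExpression <- function(cfg) {
  .simSeed(cfg, 1L)
  G <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(G))

  ## isoform structure
  nMulti <- round(cfg$frac_multi_isoform * G)
  multi <- sort(sample(G, nMulti))
  nIso <- rep(1L, G)
  nIso[multi] <- sample(2:4, nMulti, replace = TRUE)
  isoGene <- rep(genes, nIso)
  isoIdx <- sequence(nIso)
  isoforms <- sprintf("%s.%d", isoGene, isoIdx)

  ## cell-type signatures; markers drawn from genes left out of the DE pool
  base <- stats::rlnorm(G, meanlog = log(30), sdlog = log(2.5))
  typeFac <- matrix(2^stats::rnorm(G * 6, 0, 0.25), G, 6,
                    dimnames = list(genes, CELL_TYPES))
  markerIdx <- sample(G, 6 * cfg$markers_per_type)
  markers <- split(genes[markerIdx],
                   factor(rep(CELL_TYPES, each = cfg$markers_per_type),
                          levels = CELL_TYPES))
  for (k in seq_along(CELL_TYPES))
    typeFac[markers[[CELL_TYPES[k]]], k] <-
      typeFac[markers[[CELL_TYPES[k]]], k] * cfg$marker_fold
  sig <- base * typeFac                       # G x 6 signature matrix

  ## stage-DE genes: RBP panel (fetal-biased) + others, never markers
  nonMarker <- setdiff(seq_len(G), markerIdx)
  dePool <- sample(nonMarker, cfg$n_stage_de)
  rbpIdx <- dePool[seq_len(cfg$n_rbp)]
  lfc <- stats::runif(cfg$n_stage_de, cfg$lfc_range[1], cfg$lfc_range[2])
  sgn <- ifelse(stats::runif(cfg$n_stage_de) <
                  ifelse(seq_len(cfg$n_stage_de) <= cfg$n_rbp,
                         cfg$rbp_fetal_bias, 0.5), 1, -1)
  stageLfc <- numeric(G)
  stageLfc[dePool] <- sgn * lfc

  ## samples
  nPer <- c("iPSC-CVPC" = cfg$n_ipsc, "adult_heart" = cfg$n_heart,
            "adult_arteria" = cfg$n_arteria,
            "HF_pre" = cfg$n_hf_pairs, "HF_post" = cfg$n_hf_pairs)
  tissue <- rep(names(nPer), nPer)
  S <- length(tissue)
  sid <- sprintf("S%03d", seq_len(S))
  subj <- character(S)
  hf <- tissue %in% c("HF_pre", "HF_post")
  subj[!hf] <- sprintf("SUBJ%03d", seq_len(sum(!hf)))
  subj[tissue == "HF_pre"] <- sprintf("HF%02d", seq_len(cfg$n_hf_pairs))
  subj[tissue == "HF_post"] <- sprintf("HF%02d", seq_len(cfg$n_hf_pairs))
  pctMito <- stats::runif(S, 0.05, 0.25)
  samples <- data.frame(
    sample_id = sid, subject_id = subj, tissue = tissue,
    sex = sample(c("F", "M"), S, replace = TRUE),
    total_reads = round(stats::rlnorm(S, log(3e7), 0.2)),
    pct_autosomal = 1 - pctMito - stats::runif(S, 0, 0.02),
    pct_mito = pctMito, stringsAsFactors = FALSE)

  ## per-sample cell-type proportions
  props <- matrix(NA_real_, S, 6, dimnames = list(sid, CELL_TYPES))
  for (tt in names(nPer)) {
    idx <- which(tissue == tt)
    if (length(idx))
      props[idx, ] <- .rdirichlet(length(idx),
                                  stats::setNames(cfg$dirichlet[[tt]],
                                                  CELL_TYPES))
  }

  ## stage factor per sample: full effect in fetal-like samples; RBP-panel
  ## genes partially revert at the gene level in pre-LVAD samples
  stageFac <- matrix(1, G, S)
  stageFac[, tissue == "iPSC-CVPC"] <- 2^stageLfc
  preCols <- which(tissue == "HF_pre")
  stageFac[rbpIdx, preCols] <-
    2^(stageLfc[rbpIdx] * cfg$hf_reversion_rho)

  noise <- matrix(2^stats::rnorm(G * S, 0, cfg$sigma), G, S)
  geneTpm <- (sig %*% t(props)) * stageFac * noise
  dimnames(geneTpm) <- list(genes, sid)

  ## isoform usage targets per tissue group; switch genes need >= 3 isoforms
  ## so that both members of the switching pair can be minor in one stage
  ## and major in the other (a true reciprocal switch)
  multi3 <- multi[nIso[multi] >= 3L]
  if (length(multi3) < cfg$n_switch + cfg$n_hf_switch)
    stop("not enough genes with >= 3 isoforms for the requested switches")
  switchGenes <- sample(multi3, cfg$n_switch)
  hfGenes <- sample(setdiff(multi3, switchGenes), cfg$n_hf_switch)
  nRevert <- round(cfg$hf_reversion_rho * cfg$n_switch)
  revertGenes <- if (nRevert) switchGenes[seq_len(nRevert)] else integer(0)
  delta <- stats::runif(cfg$n_switch, cfg$delta_range[1], cfg$delta_range[2])
  names(delta) <- genes[switchGenes]
  deltaHf <- stats::runif(cfg$n_hf_switch, cfg$delta_range[1],
                          cfg$delta_range[2])
  names(deltaHf) <- genes[hfGenes]

  usageTargets <- vector("list", G)   # per gene: K x 5 tissue target matrix
  tissues <- names(nPer)
  switchIso <- character(0); switchPartner <- character(0)
  for (gi in seq_len(G)) {
    K <- nIso[gi]
    if (K == 1L) next
    u <- .rdirichlet(1, rep(3, K))[1, ]
    tgt <- matrix(u, K, 5, dimnames = list(NULL, tissues))
    g <- genes[gi]
    if (gi %in% switchGenes) {
      d <- delta[[g]]
      lo <- 0.05
      rest <- rep((1 - 2 * lo - d) / (K - 2), K - 2)
      adult <- c(lo, lo + d, rest)        # isoform 1 minor, isoform 2 major
      fetal <- c(lo + d, lo, rest)        # reciprocal in the fetal-like stage
      tgt <- cbind("iPSC-CVPC" = fetal, "adult_heart" = adult,
                   "adult_arteria" = adult, "HF_pre" = adult,
                   "HF_post" = adult)
      if (gi %in% revertGenes)
        tgt[, "HF_pre"] <- adult + cfg$hf_reversion_strength * (fetal - adult)
      switchIso <- c(switchIso, sprintf("%s.1", g))
      switchPartner <- c(switchPartner, sprintf("%s.2", g))
    } else if (gi %in% hfGenes) {
      d <- deltaHf[[g]]
      lo <- 0.05
      rest <- rep((1 - 2 * lo - d) / (K - 2), K - 2)
      healthy <- c(lo, lo + d, rest)
      pre <- c(lo + d, lo, rest)
      tgt <- cbind("iPSC-CVPC" = healthy, "adult_heart" = healthy,
                   "adult_arteria" = healthy, "HF_pre" = pre,
                   "HF_post" = healthy)
    }
    usageTargets[[gi]] <- tgt
  }

  ## per-sample usage draws (Dirichlet around the tissue target) and
  ## isoform TPM = usage x gene TPM, so isoforms sum exactly to the gene
  isoTpm <- matrix(NA_real_, length(isoforms), S,
                   dimnames = list(isoforms, sid))
  usageMat <- matrix(NA_real_, length(isoforms), S,
                     dimnames = list(isoforms, sid))
  tIdx <- match(tissue, tissues)
  row0 <- c(0L, cumsum(nIso))
  conc <- cfg$usage_concentration
  for (gi in seq_len(G)) {
    K <- nIso[gi]
    rows <- (row0[gi] + 1L):(row0[gi] + K)
    if (K == 1L) {
      usageMat[rows, ] <- 1
      isoTpm[rows, ] <- geneTpm[gi, ]
      next
    }
    alpha <- usageTargets[[gi]][, tIdx, drop = FALSE] * conc  # K x S
    draws <- matrix(stats::rgamma(K * S, shape = alpha), K, S)
    u <- draws / rep(colSums(draws), each = K)
    usageMat[rows, ] <- u
    isoTpm[rows, ] <- u * rep(geneTpm[gi, ], each = K)
  }

  truth <- list(
    proportions = props,
    de_genes = data.frame(gene_id = genes[dePool], lfc = sgn * lfc,
                          is_rbp = seq_len(cfg$n_stage_de) <= cfg$n_rbp,
                          stringsAsFactors = FALSE),
    rbp_genes = genes[rbpIdx],
    null_genes = genes[setdiff(seq_len(G), dePool)],
    markers = markers,
    signatures = sig,
    switch_isoforms = data.frame(
      iso_id = switchIso, partner_id = switchPartner,
      gene_id = genes[switchGenes],
      delta = as.numeric(delta[genes[switchGenes]]),
      reverts = switchGenes %in% revertGenes, stringsAsFactors = FALSE),
    hf_switch_genes = genes[hfGenes],
    switch_genes = genes[switchGenes],
    multi_isoform_genes = genes[multi],
    usage = usageMat,
    n_iso = stats::setNames(nIso, genes))

  list(gene_tpm = FeatureMatrix(geneTpm, "tpm"),
       iso_tpm = FeatureMatrix(isoTpm, "tpm"),
       samples = samples, truth = truth)
}

## ---- annotation phase -----------------------------------------------------

.simAnnotation <- function(cfg, out) {
  .simSeed(cfg, 2L)
  genes <- featureIds(out$gene_tpm)
  nIso <- out$truth$n_iso
  G <- length(genes)
  nShared <- 4L
  cursor <- new.env()
  chromOf <- paste0("chr", ceiling(seq_len(G) / 100))
  exonId <- character(0); exonChr <- character(0)
  exonStart <- integer(0); exonEnd <- integer(0); exonStrand <- character(0)
  txList <- list(); txGene <- character(0)
  geneStrand <- sample(c("+", "-"), G, replace = TRUE)
  uniqueExonOf <- vector("list", G)  # per gene: unique exon id per isoform
  for (gi in seq_len(G)) {
    chr <- chromOf[gi]
    pos <- get0(chr, envir = cursor, ifnotfound = 1000L)
    K <- nIso[[gi]]
    E <- nShared + if (K > 1L) K else 1L
    w <- sample(100:200, E, replace = TRUE)
    gaps <- sample(250:500, E, replace = TRUE)
    st <- integer(E); en <- integer(E)
    for (e in seq_len(E)) {
      st[e] <- pos
      en[e] <- pos + w[e] - 1L
      pos <- en[e] + gaps[e]
    }
    assign(chr, pos + 500L, envir = cursor)
    ids <- sprintf("%s:e%d", genes[gi], seq_len(E))
    exonId <- c(exonId, ids); exonChr <- c(exonChr, rep(chr, E))
    exonStart <- c(exonStart, st); exonEnd <- c(exonEnd, en)
    strandG <- geneStrand[gi]
    exonStrand <- c(exonStrand, rep(strandG, E))
    ## genomic exon layout: shared s1, unique u1..uK (internal), shared rest
    if (K > 1L) {
      uniqIdx <- 1L + seq_len(K)          # positions 2..K+1 are unique
      uniqueExonOf[[gi]] <- ids[uniqIdx]
      for (k in seq_len(K)) {
        keep <- c(setdiff(seq_len(E), uniqIdx), uniqIdx[k])
        keep <- sort(keep)
        exv <- ids[keep]
        if (strandG == "-") exv <- rev(exv)
        txList[[sprintf("%s.%d", genes[gi], k)]] <- exv
        txGene[sprintf("%s.%d", genes[gi], k)] <- genes[gi]
      }
    } else {
      exv <- ids
      if (strandG == "-") exv <- rev(exv)
      txList[[sprintf("%s.1", genes[gi])]] <- exv
      txGene[sprintf("%s.1", genes[gi])] <- genes[gi]
    }
  }
  exons <- GRanges(exonChr, IRanges(exonStart, exonEnd), strand = exonStrand)
  names(exons) <- exonId
  geneDf <- data.frame(gene_id = genes, gene_name = genes,
                       strand = geneStrand, stringsAsFactors = FALSE)
  rownames(geneDf) <- genes
  out$annotation <- new("TranscriptAnnotation", genes = geneDf,
                        transcripts = txList, txGene = txGene, exons = exons)
  ## ground-truth specific exons of the switch pair (isoform 1 = fetal-up)
  swg <- match(out$truth$switch_genes, genes)
  out$truth$fetal_exons <- vapply(uniqueExonOf[swg], `[`, character(1), 1)
  out$truth$adult_exons <- vapply(uniqueExonOf[swg], `[`, character(1), 2)
  out$truth$chrom_lengths <- vapply(
    unique(chromOf), function(ch) get(ch, envir = cursor) + 200L, integer(1))
  out
}

## ---- genome phase ---------------------------------------------------------

.plantSeq <- function(chars, pos0, seq, strand) {
  ## write seq (5'->3' on the transcribed strand) at 0-based pos0..
  s <- strsplit(seq, "")[[1]]
  if (strand == "-")
    s <- rev(c(A = "T", C = "G", G = "C", T = "A")[s])
  idx <- pos0 + seq_along(s)
  ok <- idx >= 1 & idx <= length(chars)
  chars[idx[ok]] <- s[ok]
  chars
}

.simGenome <- function(cfg, out) {
  .simSeed(cfg, 3L)
  lens <- out$truth$chrom_lengths
  chars <- lapply(lens, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  ## canonical splice dinucleotides around most exons (GT donor / AG acceptor
  ## in transcription orientation; minus-strand sites are stored as their
  ## reverse complement on the plus strand)
  ex <- annExons(out$annotation)
  str <- as.character(strand(ex))
  chr <- as.character(seqnames(ex))
  plant <- stats::runif(length(ex)) < 0.8
  plus <- plant & str == "+"
  minus <- plant & str == "-"
  pos <- c(end(ex)[plus] + 1L, end(ex)[plus] + 2L,       # donor GT
           start(ex)[plus] - 2L, start(ex)[plus] - 1L,   # acceptor AG
           start(ex)[minus] - 2L, start(ex)[minus] - 1L, # donor rc = AC
           end(ex)[minus] + 1L, end(ex)[minus] + 2L)     # acceptor rc = CT
  base <- c(rep(c("G", "T", "A", "G"), each = sum(plus)),
            rep(c("A", "C", "C", "T"), each = sum(minus)))
  pchr <- c(rep(chr[plus], 4), rep(chr[minus], 4))
  for (ch in unique(pchr)) {
    i <- pchr == ch
    ok <- pos[i] >= 1 & pos[i] <= lens[[ch]]
    chars[[ch]][pos[i][ok]] <- base[i][ok]
  }
  out$genome <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  names(out$genome) <- names(lens)
  out
}

## ---- peaks ----------------------------------------------------------------

.simPeaks <- function(cfg, out) {
  .simSeed(cfg, 4L)
  bodies <- geneBodyIntervals(out$annotation)
  spec <- names(bodies) %in% out$truth$switch_genes
  prob <- ifelse(spec, cfg$peak_prob_specific, cfg$peak_prob_background)
  out$peaks <- lapply(seq_len(cfg$n_eclip), function(e) {
    hit <- stats::runif(length(bodies)) < prob
    b <- bodies[hit]
    w <- sample(50:150, length(b), replace = TRUE)
    off <- floor(stats::runif(length(b)) * pmax(width(b) - w, 1))
    gr <- GRanges(seqnames(b), IRanges(start(b) + off, width = w))
    PeakSet(gr, sprintf("ECLIP%02d", e), sprintf("RBP%d", e), "synthCell")
  })
  out$truth$peak_enriched_genes <- names(bodies)[spec]
  out
}

## ---- motifs ---------------------------------------------------------------

.simMotifs <- function(cfg, out) {
  .simSeed(cfg, 5L)
  mk <- function(consensus, id, rbp) {
    L <- nchar(consensus)
    m <- matrix(0.05, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    cb <- strsplit(consensus, "")[[1]]
    for (j in seq_len(L)) m[cb[j], j] <- 0.85
    PWMotif(m, id, rbp)
  }
  motifs <- list(mk("TGCATG", "M1", "RBPX"), mk("ACGTAC", "M2", "RBPY"),
                 mk("GGACTT", "M3", "RBPZ"), mk("TTAGCCA", "M4", "RBPW"),
                 mk("CAGTCG", "M5", "RBPV"), mk("ATCGAT", "M6", "RBPU"))
  ## plant motif 1 in acceptor windows (100 bp upstream of exon start,
  ## transcription orientation) of the tissue-specific exons
  ex <- annExons(out$annotation)
  chars <- lapply(as.character(out$genome), function(s) strsplit(s, "")[[1]])
  consensus <- strsplit("TGCATG", "")[[1]]
  consRc <- rev(c(A = "T", C = "G", G = "C", T = "A")[consensus])
  plantWin <- function(eids, p) {
    hit <- eids[stats::runif(length(eids)) < p]
    if (!length(hit)) return(hit)
    e <- ex[hit]
    str <- as.character(strand(e))
    chrs <- as.character(seqnames(e))
    off <- sample(10:80, length(hit), replace = TRUE)
    ## 1-based first position of the planted hexamer on the plus strand
    p1 <- ifelse(str == "+", start(e) - off - 6L, end(e) + off + 1L)
    for (ch in unique(chrs)) {
      i <- which(chrs == ch)
      idx <- rep(p1[i], each = 6L) + 0:5
      b <- unlist(lapply(i, function(j)
        if (str[j] == "+") consensus else consRc), use.names = FALSE)
      ok <- idx >= 1 & idx <= length(chars[[ch]])
      chars[[ch]][idx[ok]] <<- b[ok]
    }
    hit
  }
  fetalHit <- plantWin(out$truth$fetal_exons, cfg$motif_prob_specific)
  adultHit <- plantWin(out$truth$adult_exons, cfg$motif_prob_background)
  out$genome <- Biostrings::DNAStringSet(
    vapply(chars, paste, character(1), collapse = ""))
  out$motifs <- motifs
  out$truth$motif_planted <- list(motif_id = "M1", fetal = fetalHit,
                                  adult = adultHit)
  out
}

## ---- gene sets ------------------------------------------------------------

.simGeneSets <- function(cfg, out) {
  .simSeed(cfg, 6L)
  genes <- featureIds(out$gene_tpm)
  sets <- list(RBP_BINDING = out$truth$rbp_genes)
  for (i in seq_len(cfg$n_gene_sets))
    sets[[sprintf("RANDOM_SET_%02d", i)]] <-
      sample(genes, sample(20:100, 1))
  attr(sets, "collection") <- c("custom", rep("random", cfg$n_gene_sets))
  out$gene_sets <- sets
  out
}

## ---- domains --------------------------------------------------------------

.simDomains <- function(cfg, out) {
  .simSeed(cfg, 7L)
  ex <- annExons(out$annotation)
  mkOver <- function(eids, p) {
    hit <- eids[stats::runif(length(eids)) < p]
    e <- ex[hit]
    GRanges(seqnames(e), IRanges(start(e) + 10L, end(e) - 10L))
  }
  d1 <- mkOver(out$truth$fetal_exons, cfg$domain_prob_specific)
  d2 <- mkOver(out$truth$adult_exons, cfg$domain_prob_background)
  ## background domains scattered between genes
  chrs <- names(out$truth$chrom_lengths)
  bg <- GRanges(sample(chrs, 200, replace = TRUE),
                IRanges(sample(1000:50000, 200, replace = TRUE), width = 120))
  dom <- c(d1, d2, bg)
  dom$domain_name <- sprintf("DOM%04d", seq_along(dom))
  out$domains <- dom
  out
}

## ---- single-cell fixture --------------------------------------------------

.simSingleCell <- function(cfg, out) {
  .simSeed(cfg, 8L)
  sig <- out$truth$signatures
  G <- nrow(sig)
  nc <- cfg$sc_cells_per_type
  labels <- rep(CELL_TYPES, each = nc)
  counts <- matrix(0L, G, length(labels),
                   dimnames = list(rownames(sig),
                                   sprintf("cell%04d", seq_along(labels))))
  size <- 1 / cfg$sc_dispersion
  for (k in seq_along(CELL_TYPES)) {
    mu <- sig[, k] / sum(sig[, k]) * cfg$sc_depth
    cols <- (k - 1L) * nc + seq_len(nc)
    counts[, cols] <- matrix(
      stats::rnbinom(G * nc, mu = mu, size = size), G, nc)
  }
  out$sc_counts <- counts
  out$sc_labels <- stats::setNames(labels, colnames(counts))
  out
}

## ---- splice-site set simulator -------------------------------------------

#' Default positional composition for a simulated splice-site set
#'
#' Positions are indexed in transcription orientation: acceptor positions
#' -100..-1 upstream of the exon start, donor positions +1..+100 downstream
#' of the exon end. The default profile has canonical GT at donor +1/+2,
#' canonical AG at acceptor -2/-1 and a thymine-rich polypyrimidine tract at
#' acceptor -25..-5.
#'
#' @param donor_gt,acceptor_ag probability of the canonical dinucleotide
#'   bases.
#' @param ppt_t per-position probability of thymine inside the
#'   polypyrimidine tract.
#' @param overrides named list like \code{list(donor = list("1" = c(G =
#'   0.95)))} replacing individual positions.
#' @return list with \code{donor} and \code{acceptor} position maps.
#' @export
spliceSetProfile <- function(donor_gt = 0.8, acceptor_ag = 0.8, ppt_t = 0.55,
                             overrides = list()) {
  donor <- list("1" = c(G = donor_gt), "2" = c(T = donor_gt))
  acceptor <- list("-2" = c(A = acceptor_ag), "-1" = c(G = acceptor_ag))
  for (p in -25:-5) acceptor[[as.character(p)]] <- c(T = ppt_t)
  for (nm in names(overrides$donor)) donor[[nm]] <- overrides$donor[[nm]]
  for (nm in names(overrides$acceptor))
    acceptor[[nm]] <- overrides$acceptor[[nm]]
  list(donor = donor, acceptor = acceptor)
}

#' Simulate two exon sets with controlled splice-site composition
#'
#' Builds a synthetic chromosome carrying \code{n_exons} exons per set; at
#' each specified flanking position the canonical base is drawn with the
#' set's probability (other bases uniform), and unspecified positions are
#' uniform. Exon strands are randomized; the emitted genome and exon
#' coordinates are consistent so windows are extractable downstream.
#'
#' @param n_exons exons per set (a length-2 vector recycles from one value).
#' @param profiles list of two position maps (see
#'   \code{\link{spliceSetProfile}}).
#' @param seed integer seed.
#' @param exon_width exon width in bp.
#' @return list with \code{genome} (DNAStringSet), \code{exons} (named
#'   GRanges), \code{pair} (exon-set pair usable by
#'   \code{\link{spliceProfiles}}) and \code{truth} (data.frame of positions
#'   whose composition differs between the sets).
#' @export
simulateSpliceSets <- function(n_exons,
                               profiles = list(spliceSetProfile(),
                                               spliceSetProfile()),
                               seed = 1, exon_width = 150) {
  stopifnot(length(profiles) == 2)
  n_exons <- rep_len(n_exons, 2L)
  badP <- unlist(lapply(profiles, function(p) unlist(p)), use.names = FALSE)
  if (length(badP) && (any(badP < 0) | any(badP > 1)))
    stop("positional probabilities must lie in [0, 1]")
  set.seed(seed)
  total <- sum(n_exons)
  unit <- exon_width + 300L            # 100bp flanks + spacing
  glen <- max(total * unit + 400L, 1000L)
  chars <- sample(c("A", "C", "G", "T"), glen, replace = TRUE)
  starts <- 200L + (seq_len(total) - 1L) * unit
  strands <- sample(c("+", "-"), total, replace = TRUE)
  if (total == 0L) {
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chars, collapse = ""), "chrS"))
    exons <- GRanges()
    pair <- exonSetPair(character(0), character(0), "set1", "set2",
                        label = "simulated")
    return(list(genome = genome, exons = exons, pair = pair,
                truth = NULL))
  }
  setOf <- rep(1:2, n_exons)
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  drawBases <- function(n, spec) {
    b <- names(spec)[1]
    others <- setdiff(bases, b)
    ifelse(stats::runif(n) < spec[[1]], b,
           others[sample.int(3, n, replace = TRUE)])
  }
  for (s in 1:2) {
    idx <- which(setOf == s)
    st <- starts[idx]; en <- st + exon_width - 1L
    plus <- strands[idx] == "+"
    pr <- profiles[[s]]
    for (side in c("acceptor", "donor")) {
      for (pn in names(pr[[side]])) {
        p <- as.integer(pn)
        b <- drawBases(length(idx), pr[[side]][[pn]])
        gpos <- if (side == "acceptor") ifelse(plus, st + p, en - p)
                else ifelse(plus, en + p, st - p)
        b[!plus] <- comp[b[!plus]]
        chars[gpos] <- b
      }
    }
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(chars, collapse = ""), "chrS"))
  exons <- GRanges("chrS", IRanges(starts, width = exon_width),
                   strand = strands)
  names(exons) <- sprintf("set%d_e%04d", setOf, sequence(n_exons))
  pair <- exonSetPair(names(exons)[setOf == 1], names(exons)[setOf == 2],
                      tissue1 = "set1", tissue2 = "set2",
                      label = "simulated")
  ## record planted differing positions
  truth <- list()
  for (side in c("donor", "acceptor")) {
    pos <- union(names(profiles[[1]][[side]]), names(profiles[[2]][[side]]))
    for (pn in pos) {
      s1 <- profiles[[1]][[side]][[pn]]; s2 <- profiles[[2]][[side]][[pn]]
      b <- if (is.null(s1)) names(s2)[1] else names(s1)[1]
      p1 <- if (is.null(s1)) 0.25 else unname(s1[1])
      p2 <- if (is.null(s2)) 0.25 else unname(s2[1])
      truth[[length(truth) + 1L]] <- data.frame(
        side = side, position = as.integer(pn),
        base = b, p1 = p1, p2 = p2,
        differs = abs(p1 - p2) > 1e-12, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  list(genome = genome, exons = exons, pair = pair, truth = truth)
}
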