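## Readers and writers for every external format the pipeline touches, plus
## the coordinate/strand primitives. Internal interval containers are GRanges
## (1-based closed); GTF and BED conversions happen here at the boundary.

VALID_TISSUES <- c("iPSC-CVPC", "adult_heart", "adult_arteria",
                   "HF_pre", "HF_post")

#' Read a sample table
#'
#' Expects a TSV with header columns \code{sample_id}, \code{subject_id},
#' \code{tissue}, \code{sex}, \code{total_reads}, \code{pct_autosomal},
#' \code{pct_mito}. Rows are validated (unique sample ids, known tissue
#' labels, fraction sanity) and returned in file order.
#'
#' @param path path to the TSV file.
#' @return data.frame of validated sample records.
#' @export
readSampleTable <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validateSampleTable(df)
}

#' Validate a sample table already held as a data.frame
#'
#' @param df data.frame with the sample-table columns.
#' @return the validated data.frame (row order preserved).
#' @export
validateSampleTable <- function(df) {
  req <- c("sample_id", "subject_id", "tissue", "sex", "total_reads",
           "pct_autosomal", "pct_mito")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("sample table is missing columns: ", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  bad <- !df$tissue %in% VALID_TISSUES
  if (any(bad))
    stop("unknown tissue label in row(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(df$tissue[bad]), collapse = ", "))
  if (!all(df$sex %in% c("F", "M")))
    stop("sex must be 'F' or 'M'")
  fracBad <- df$pct_autosomal < 0 | df$pct_autosomal > 1 |
    df$pct_mito < 0 | df$pct_mito > 1
  if (any(fracBad))
    stop("pct_autosomal / pct_mito outside [0, 1] in row(s) ",
         paste(which(fracBad), collapse = ", "))
  sumBad <- df$pct_autosomal + df$pct_mito > 1 + 1e-9
  if (any(sumBad))
    stop("pct_autosomal + pct_mito > 1 in row(s) ",
         paste(which(sumBad), collapse = ", "))
  df
}

#' Write / read a FeatureMatrix as TSV
#'
#' Values are serialized with 17 significant digits so a write/read round trip
#' is bit-exact. The measurement kind travels in a \code{# kind:} header line.
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param path output path.
#' @return \code{writeFeatureMatrix} returns \code{path} invisibly;
#'   \code{readFeatureMatrix} returns a \linkS4class{FeatureMatrix}.
#' @export
writeFeatureMatrix <- function(x, path) {
  stopifnot(is(x, "FeatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind: ", x@kind), con)
  v <- as.matrix(x)
  writeLines(paste(c("feature_id", colnames(v)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], format(v[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub("^# kind: *", "", first)
  df <- utils::read.delim(path, skip = 1L, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  FeatureMatrix(v, kind)
}

#' Read a Gencode-dialect GTF into a TranscriptAnnotation
#'
#' Exon lines must carry \code{gene_id}, \code{transcript_id} and
#' \code{exon_id} attributes. Exons with identical coordinates collapse to one
#' record (they are expected to share the same exon id, as in Gencode); an
#' exon id reused for different coordinates is an error, as is a transcript
#' spanning mixed strands. Exon order within a transcript is 5'->3' in
#' transcription orientation.
#'
#' @param path path to the GTF file (1-based closed coordinates).
#' @return A \linkS4class{TranscriptAnnotation}.
#' @export
readGtfAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon records in ", path)
  need <- c("gene_id", "transcript_id", "exon_id")
  miss <- setdiff(need, colnames(S4Vectors::mcols(gr)))
  if (length(miss))
    stop("GTF exon lines lack attribute(s): ", paste(miss, collapse = ", "))
  key <- paste(as.character(seqnames(gr)), start(gr), end(gr),
               as.character(strand(gr)), sep = ":")
  ids <- gr$exon_id
  ## one id -> one coordinate set
  byId <- split(key, ids)
  clash <- names(byId)[vapply(byId, function(k) length(unique(k)) > 1L,
                              logical(1))]
  if (length(clash))
    stop("exon_id reused for differing coordinates: ",
         paste(utils::head(clash, 3), collapse = ", "))
  keep <- !duplicated(ids)
  exons <- GRanges(seqnames(gr)[keep],
                   IRanges(start(gr)[keep], end(gr)[keep]),
                   strand = strand(gr)[keep])
  names(exons) <- ids[keep]

  txStrand <- split(as.character(strand(gr)), gr$transcript_id)
  mixed <- names(txStrand)[vapply(txStrand,
                                  function(s) length(unique(s)) > 1L,
                                  logical(1))]
  if (length(mixed))
    stop("transcript(s) on mixed strands: ",
         paste(utils::head(mixed, 3), collapse = ", "))

  ord <- order(gr$transcript_id, start(gr))
  txList <- split(ids[ord], gr$transcript_id[ord])
  minus <- vapply(txStrand, function(s) s[1] == "-", logical(1))
  txList[minus[names(txList)]] <- lapply(txList[minus[names(txList)]], rev)
  txGene <- vapply(split(gr$gene_id, gr$transcript_id), `[`, character(1), 1)

  gname <- if ("gene_name" %in% colnames(S4Vectors::mcols(gr)))
    gr$gene_name else gr$gene_id
  gkeep <- !duplicated(gr$gene_id)
  genes <- data.frame(gene_id = gr$gene_id[gkeep],
                      gene_name = gname[gkeep],
                      strand = as.character(strand(gr))[gkeep],
                      stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene_id
  new("TranscriptAnnotation", genes = genes, transcripts = as.list(txList),
      txGene = txGene, exons = exons)
}

#' Read a BED6 file of eCLIP peaks
#'
#' BED is 0-based half-open on disk; intervals are converted to the GRanges
#' convention on read. The RBP name is parsed from the name column
#' (\code{RBP_cellline_rep} dialect) unless given explicitly.
#'
#' @param path path to the BED file.
#' @param experiment_id experiment label (default: file base name).
#' @param rbp_name,cell_line overrides for metadata parsed from the name
#'   column; missing metadata defaults to "NA".
#' @return A \linkS4class{PeakSet}.
#' @export
readBedPeaks <- function(path, experiment_id = NULL, rbp_name = NULL,
                         cell_line = NULL) {
  if (is.null(experiment_id))
    experiment_id <- sub("\\.bed$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(PeakSet(GRanges(), experiment_id,
                   rbp_name %||% "NA", cell_line %||% "NA"))
  }
  parts <- strsplit(lines, "\t")
  n <- vapply(parts, length, integer(1))
  if (any(n < 3)) stop("BED line ", which(n < 3)[1], " has fewer than 3 fields")
  chrom <- vapply(parts, `[`, character(1), 1)
  s0 <- as.integer(vapply(parts, `[`, character(1), 2))
  e0 <- as.integer(vapply(parts, `[`, character(1), 3))
  bad <- which(s0 >= e0)
  if (length(bad))
    stop("BED line ", bad[1], ": start >= end (", s0[bad[1]], " >= ",
         e0[bad[1]], ")")
  nameCol <- ifelse(n >= 4, vapply(parts, function(p) p[4], character(1)), NA)
  if (is.null(rbp_name)) {
    toks <- strsplit(nameCol[1], "_")[[1]]
    rbp_name <- if (!is.na(nameCol[1]) && length(toks) >= 1) toks[1] else "NA"
  }
  if (is.null(cell_line)) {
    toks <- strsplit(nameCol[1], "_")[[1]]
    cell_line <- if (!is.na(nameCol[1]) && length(toks) >= 2) toks[2] else "NA"
  }
  PeakSet(GRanges(chrom, IRanges(s0 + 1L, e0)), experiment_id, rbp_name,
          cell_line)
}

#' Write a PeakSet as BED6 (0-based half-open)
#' @param x a \linkS4class{PeakSet}
#' @param path output path
#' @export
writeBedPeaks <- function(x, path) {
  gr <- peakRanges(x)
  lines <- sprintf("%s\t%d\t%d\t%s_%s\t0\t.", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr), x@rbp_name, x@cell_line)
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a sequence window around a genomic boundary
#'
#' The anchor is a 0-based inter-base boundary (e.g. the 0-based start of an
#' exon, or its 0-based end, which equals the 1-based end coordinate). Side
#' \code{"up"} / \code{"down"} is interpreted in transcription orientation:
#' on the plus strand "up" is the \code{length} bases before the anchor; on
#' the minus strand "up" is the \code{length} bases after it, reverse
#' complemented. The returned string reads 5'->3' on the transcribed strand.
#' Windows crossing a chromosome edge are truncated, with
#' \code{attr(, "truncated") = TRUE} and a warning.
#'
#' @param genome a named \code{DNAStringSet} (one entry per chromosome).
#' @param chrom chromosome name.
#' @param anchor 0-based boundary coordinate.
#' @param length window length in bases.
#' @param side \code{"up"} or \code{"down"} of the anchor, in transcription
#'   orientation.
#' @param strand \code{"+"} or \code{"-"}.
#' @return Uppercase character string (possibly truncated), with attributes
#'   \code{truncated} and \code{offset} (bases lost at the far edge).
#' @export
extractWindow <- function(genome, chrom, anchor, length,
                          side = c("up", "down"), strand = c("+", "-")) {
  side <- match.arg(side)
  strand <- match.arg(strand)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  clen <- Biostrings::width(genome[chrom])
  ## genomic (0-based half-open) window before reverse-complementing
  upstreamInGenome <- (side == "up") == (strand == "+")
  if (upstreamInGenome) {
    s0 <- anchor - length; e0 <- anchor
  } else {
    s0 <- anchor; e0 <- anchor + length
  }
  truncated <- s0 < 0 || e0 > clen
  s0c <- max(s0, 0L); e0c <- min(e0, clen)
  if (e0c <= s0c) {
    out <- ""
  } else {
    seq <- Biostrings::subseq(genome[[chrom]], start = s0c + 1L, end = e0c)
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    out <- toupper(as.character(seq))
  }
  if (truncated) warning("window truncated at chromosome edge (", chrom, ")")
  attr(out, "truncated") <- truncated
  out
}

#' Gene body intervals
#'
#' Per gene, the span from the smallest exon start to the largest exon end
#' over all its transcripts. Genes with zero exons are excluded with a
#' warning.
#'
#' @param ann a \linkS4class{TranscriptAnnotation}.
#' @return GRanges named by gene id.
#' @export
geneBodyIntervals <- function(ann) {
  ex <- annExons(ann)
  stopifnot(length(ex) > 0)
  txs <- annTranscripts(ann)
  eid <- unlist(txs, use.names = FALSE)
  gid <- rep(unname(txToGene(ann)[names(txs)]), lengths(txs))
  keep <- !duplicated(paste0(gid, "\r", eid))
  eid <- eid[keep]; gid <- gid[keep]
  empty <- setdiff(annGenes(ann)$gene_id, gid)
  if (length(empty))
    warning("gene(s) with zero exons excluded: ",
            paste(utils::head(empty, 3), collapse = ", "))
  i <- match(eid, names(ex))
  f <- factor(gid)
  gr <- GRanges(
    tapply(as.character(seqnames(ex))[i], f, `[`, 1),
    IRanges(as.integer(tapply(start(ex)[i], f, min)),
            as.integer(tapply(end(ex)[i], f, max))),
    strand = tapply(as.character(strand(ex))[i], f, `[`, 1))
  names(gr) <- levels(f)
  gr
}

#' Read / write gene sets in GMT format
#'
#' Each GMT line is \code{name<TAB>description<TAB>member...}; the description
#' field carries the collection label. Gene sets are returned as a named list
#' of character vectors with a \code{collection} attribute, the convention
#' used by fgsea-style tooling.
#'
#' @param path file path.
#' @return named list of gene-id vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("GMT line ", which(bad)[1], " has no members")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "collection") <- vapply(parts, `[`, character(1), 2)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param collection collection label(s), recycled.
#' @export
writeGmt <- function(sets, path, collection = "custom") {
  collection <- rep_len(attr(sets, "collection") %||% collection,
                        length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], collection[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write RBP motifs in MEME-minimal format
#'
#' Supports the minimal MEME dialect: \code{MOTIF id name} headers followed by
#' a \code{letter-probability matrix} block with one row per motif position
#' (columns A, C, G, T).
#'
#' @param path file path.
#' @return list of \linkS4class{PWMotif} objects.
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF ", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1] - 1L)]
    hdr <- strsplit(trimws(block[1]), "\\s+")[[1]]
    motif_id <- hdr[2]
    rbp <- if (length(hdr) >= 3) hdr[3] else motif_id
    mstart <- grep("^letter-probability matrix", block)
    if (!length(mstart)) stop("motif ", motif_id, " lacks a probability matrix")
    rows <- block[-seq_len(mstart)]
    rows <- rows[grepl("^\\s*[0-9.eE+-]", rows)]
    m <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(r) as.numeric(r[1:4]), numeric(4)))
    out[[i]] <- PWMotif(t(m), motif_id, rbp)
  }
  out
}

#' @rdname readMemeMotifs
#' @param motifs list of PWMotif objects.
#' @export
writeMemeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m@motif_id, m@rbp_name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m@mat)), con)
    for (j in seq_len(ncol(m@mat)))
      writeLines(paste(format(m@mat[, j], digits = 6), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write a BED-like protein-domain table
#'
#' Columns: chrom, start, end (0-based half-open on disk), domain_name and an
#' optional strand. Domain/exon overlap tests in this package are
#' strand-blind.
#'
#' @param path file path.
#' @return GRanges with a \code{domain_name} metadata column.
#' @export
readDomainTable <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (any(df[[2]] >= df[[3]]))
    stop("domain with start >= end at line ", which(df[[2]] >= df[[3]])[1])
  gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
  gr$domain_name <- if (ncol(df) >= 4) df[[4]] else paste0("domain", seq_len(nrow(df)))
  gr
}

#' @rdname readDomainTable
#' @param domains GRanges with a \code{domain_name} column.
#' @export
writeDomainTable <- function(domains, path) {
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(domains)),
                   start(domains) - 1L, end(domains), domains$domain_name)
  writeLines(lines, path)
  invisible(path)
}

#' Write a TranscriptAnnotation as a Gencode-dialect GTF
#' @param ann a \linkS4class{TranscriptAnnotation}
#' @param path output path
#' @export
writeGtfAnnotation <- function(ann, path) {
  ex <- annExons(ann)
  txg <- txToGene(ann)
  lines <- character()
  for (tx in names(annTranscripts(ann))) {
    eids <- annTranscripts(ann)[[tx]]
    e <- ex[eids]
    gid <- txg[[tx]]
    lines <- c(lines, sprintf(
      "%s\tsynthetic\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; exon_id \"%s\"; gene_name \"%s\";",
      as.character(seqnames(e)), start(e), end(e), as.character(strand(e)),
      gid, tx, eids, annGenes(ann)[gid, "gene_name"]))
  }
  writeLines(lines, path)
  invisible(path)
}
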