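#' @import methods
#' @importFrom GenomicRanges GRanges seqnames strand start end width findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

## Central S4 containers. Expression matrices, annotation hierarchies and
## interval sets are the common currency of every stage, so they get validated
## classes; result tables are plain data.frames (one row per feature/test),
## following the limma/DESeq2 results-table convention.

#' Feature-by-sample expression matrix
#'
#' A dense nonnegative feature x sample matrix carrying its measurement kind:
#' \code{"tpm"} (transcripts per million, >= 0), \code{"usage"} (isoform usage
#' fractions in [0, 1]) or \code{"normalized"} (unbounded, e.g. after rank
#' inverse-normal transformation).
#'
#' @slot values numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids).
#' @slot kind one of \code{"tpm"}, \code{"usage"}, \code{"normalized"}.
#' @export
setClass("FeatureMatrix", slots = c(values = "matrix", kind = "character"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) > 0 && (is.null(rownames(v)) || anyDuplicated(rownames(v))))
    msgs <- c(msgs, "feature ids (rownames) must be present and unique")
  if (ncol(v) > 0 && (is.null(colnames(v)) || anyDuplicated(colnames(v))))
    msgs <- c(msgs, "sample ids (colnames) must be present and unique")
  if (length(object@kind) != 1L ||
      !object@kind %in% c("tpm", "usage", "normalized"))
    msgs <- c(msgs, "kind must be one of 'tpm', 'usage', 'normalized'")
  else if (length(v) && !anyNA(v)) {
    if (object@kind == "tpm" && any(v < 0))
      msgs <- c(msgs, "kind 'tpm' requires all values >= 0")
    if (object@kind == "usage" && (any(v < 0) || any(v > 1 + 1e-9)))
      msgs <- c(msgs, "kind 'usage' requires all values in [0, 1]")
  }
  if (anyNA(v)) msgs <- c(msgs, "values must not contain NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix (features x samples) with row and column names.
#' @param kind \code{"tpm"}, \code{"usage"} or \code{"normalized"}.
#' @return A \linkS4class{FeatureMatrix}.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' FeatureMatrix(m, "tpm")
#' @export
FeatureMatrix <- function(values, kind = c("tpm", "usage", "normalized")) {
  kind <- match.arg(kind)
  storage.mode(values) <- "double"
  new("FeatureMatrix", values = values, kind = kind)
}

#' @describeIn FeatureMatrix-class feature identifiers (rownames)
#' @param x a FeatureMatrix
#' @export
featureIds <- function(x) rownames(x@values)

#' @describeIn FeatureMatrix-class sample identifiers (colnames)
#' @export
sampleIds <- function(x) colnames(x@values)

#' @describeIn FeatureMatrix-class measurement kind
#' @export
matrixKind <- function(x) x@kind

#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix [%s]: %d features x %d samples\n", object@kind,
              nrow(object@values), ncol(object@values)))
})

#' Extract the numeric matrix of a FeatureMatrix
#' @param x a \linkS4class{FeatureMatrix}
#' @param ... ignored
#' @export
setMethod("as.matrix", "FeatureMatrix", function(x, ...) x@values)

setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

#' Subset a FeatureMatrix by features and/or samples
#' @param x a FeatureMatrix
#' @param i,j feature / sample indices (any form \code{[} accepts)
#' @param drop ignored (never drops)
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("FeatureMatrix", values = v, kind = x@kind)
})

#' Gene / transcript / exon annotation hierarchy
#'
#' Exons with identical coordinates share one exon id (the Gencode convention),
#' so an exon record can belong to several transcripts. Exon order inside a
#' transcript is 5'->3' in transcription orientation.
#'
#' @slot genes data.frame with columns gene_id, gene_name, strand.
#' @slot transcripts named list: transcript_id -> character vector of exon ids
#'   in transcription order.
#' @slot txGene named character: transcript_id -> gene_id.
#' @slot exons GRanges (1-based closed, the GRanges convention) named by
#'   exon id.
#' @export
setClass("TranscriptAnnotation",
         slots = c(genes = "data.frame", transcripts = "list",
                   txGene = "character", exons = "GRanges"))

setValidity("TranscriptAnnotation", function(object) {
  msgs <- character()
  if (!all(c("gene_id", "gene_name", "strand") %in% colnames(object@genes)))
    msgs <- c(msgs, "genes must have gene_id, gene_name, strand columns")
  if (is.null(names(object@exons)) || anyDuplicated(names(object@exons)))
    msgs <- c(msgs, "exons must be uniquely named by exon id")
  if (!setequal(names(object@transcripts), names(object@txGene)))
    msgs <- c(msgs, "transcripts and txGene must name the same transcripts")
  bad <- setdiff(unique(unlist(object@transcripts, use.names = FALSE)),
                 names(object@exons))
  if (length(bad))
    msgs <- c(msgs, paste("transcripts reference unknown exons:",
                          paste(utils::head(bad, 3), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' @export
setMethod("show", "TranscriptAnnotation", function(object) {
  cat(sprintf("TranscriptAnnotation: %d genes, %d transcripts, %d exons\n",
              nrow(object@genes), length(object@transcripts),
              length(object@exons)))
})

#' @describeIn TranscriptAnnotation-class gene table
#' @param x a TranscriptAnnotation
#' @export
annGenes <- function(x) x@genes

#' @describeIn TranscriptAnnotation-class transcript -> exon id list
#' @export
annTranscripts <- function(x) x@transcripts

#' @describeIn TranscriptAnnotation-class transcript -> gene id map
#' @export
txToGene <- function(x) x@txGene

#' @describeIn TranscriptAnnotation-class exon GRanges named by exon id
#' @export
annExons <- function(x) x@exons

#' eCLIP peak set for one experiment
#'
#' @slot experiment_id experiment identifier.
#' @slot rbp_name RNA-binding protein name.
#' @slot cell_line cell line ("NA" when unknown).
#' @slot peaks GRanges of peak intervals.
#' @export
setClass("PeakSet",
         slots = c(experiment_id = "character", rbp_name = "character",
                   cell_line = "character", peaks = "GRanges"))

#' Construct a PeakSet
#' @param peaks GRanges of peaks
#' @param experiment_id,rbp_name,cell_line experiment metadata
#' @export
PeakSet <- function(peaks, experiment_id, rbp_name, cell_line = "NA") {
  new("PeakSet", experiment_id = experiment_id, rbp_name = rbp_name,
      cell_line = cell_line, peaks = peaks)
}

#' @export
setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet %s (%s, %s): %d peaks\n", object@experiment_id,
              object@rbp_name, object@cell_line, length(object@peaks)))
})

#' @describeIn PeakSet-class peak intervals as GRanges
#' @param x a PeakSet
#' @export
peakRanges <- function(x) x@peaks

#' Position weight matrix of an RBP motif
#'
#' @slot motif_id motif identifier.
#' @slot rbp_name RBP the motif belongs to.
#' @slot mat 4 x L probability matrix, rows A, C, G, T; columns sum to 1.
#' @export
setClass("PWMotif",
         slots = c(motif_id = "character", rbp_name = "character",
                   mat = "matrix"))

setValidity("PWMotif", function(object) {
  m <- object@mat
  msgs <- character()
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    msgs <- c(msgs, "mat rows must be A, C, G, T")
  if (ncol(m) < 4) msgs <- c(msgs, "motif length must be >= 4")
  if (length(m) && any(abs(colSums(m) - 1) > 1e-6))
    msgs <- c(msgs, "each column must sum to 1 (+- 1e-6)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PWMotif
#' @param mat 4 x L probability matrix (rows A, C, G, T)
#' @param motif_id,rbp_name identifiers
#' @export
PWMotif <- function(mat, motif_id, rbp_name) {
  rownames(mat) <- c("A", "C", "G", "T")
  new("PWMotif", motif_id = motif_id, rbp_name = rbp_name, mat = mat)
}

#' @export
setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif %s (%s), length %d\n", object@motif_id,
              object@rbp_name, ncol(object@mat)))
})

#' @describeIn PWMotif-class probability matrix
#' @param x a PWMotif
#' @export
pwmMatrix <- function(x) x@mat

#' @describeIn PWMotif-class consensus sequence (highest-probability base per
#'   column)
#' @export
pwmConsensus <- function(x) {
  paste(rownames(x@mat)[apply(x@mat, 2, which.max)], collapse = "")
}
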