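test_that("sample table reader validates and preserves order", {
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = c("s3", "s1", "s2"),
                   subject_id = c("u3", "u1", "u2"),
                   tissue = c("iPSC-CVPC", "adult_heart", "HF_pre"),
                   sex = c("F", "M", "F"), total_reads = c(1e7, 2e7, 3e7),
                   pct_autosomal = c(0.8, 0.85, 0.9),
                   pct_mito = c(0.1, 0.1, 0.05))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- readSampleTable(tsv)
  expect_equal(out$sample_id, c("s3", "s1", "s2"))

  df2 <- df; df2$sample_id <- c("s1", "s1", "s2")
  write.table(df2, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(tsv), "s1")

  df3 <- df; df3$tissue[2] <- "kidney"
  write.table(df3, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(tsv), "row\\(s\\) 2")

  df4 <- df; df4$pct_mito[1] <- 0.2; df4$pct_autosomal[1] <- 0.9
  write.table(df4, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readSampleTable(tsv), "> 1")
})

test_that("FeatureMatrix enforces kind-specific invariants", {
  m <- matrix(c(0, 0.5, 1, 0.2), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_s4_class(FeatureMatrix(m, "usage"), "FeatureMatrix")
  expect_error(FeatureMatrix(m * 2, "usage"), "usage")
  expect_error(FeatureMatrix(m - 1, "tpm"), "tpm")
  dup <- m; rownames(dup) <- c("f1", "f1")
  expect_error(FeatureMatrix(dup, "tpm"), "unique")
})

test_that("FeatureMatrix TSV round trip is bit-exact", {
  set.seed(5)
  v <- matrix(rlnorm(60) * c(1, 1e-7, 1e6), 10, 6,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:6)))
  fm <- FeatureMatrix(v, "tpm")
  path <- tempfile(fileext = ".tsv")
  writeFeatureMatrix(fm, path)
  back <- readFeatureMatrix(path)
  expect_identical(as.matrix(back), as.matrix(fm))
  expect_identical(matrixKind(back), "tpm")
})

test_that("GTF reader converts coordinates and collapses shared exons", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; exon_id "e1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; exon_id "e2";',
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t2"; exon_id "e1";',
    'chr2\tx\texon\t501\t600\t.\t-\t.\tgene_id "g2"; transcript_id "t3"; exon_id "e3";',
    'chr2\tx\texon\t101\t200\t.\t-\t.\tgene_id "g2"; transcript_id "t3"; exon_id "e4";')
  writeLines(lines, gtf)
  ann <- readGtfAnnotation(gtf)
  ex <- annExons(ann)
  ## GTF [101, 200] stays 1-based closed internally (the GRanges convention);
  ## BED-style export is 0-based: start 100
  expect_equal(GenomicRanges::start(ex["e1"]), 101)
  expect_equal(GenomicRanges::end(ex["e1"]), 200)
  expect_equal(length(ex), 4L)          # e1 shared by t1 and t2
  expect_setequal(annTranscripts(ann)$t2, "e1")
  ## minus-strand transcript reported 5'->3': downstream-coordinate exon first
  expect_equal(annTranscripts(ann)$t3, c("e3", "e4"))

  bad <- c(lines,
    'chr1\tx\texon\t901\t950\t.\t+\t.\tgene_id "g1"; transcript_id "t4"; exon_id "e1";')
  writeLines(bad, gtf)
  expect_error(readGtfAnnotation(gtf), "exon_id")

  mixed <- c(lines,
    'chr1\tx\texon\t901\t950\t.\t-\t.\tgene_id "g1"; transcript_id "t1"; exon_id "e9";')
  writeLines(mixed, gtf)
  expect_error(readGtfAnnotation(gtf), "mixed strands")
})

test_that("internal exon coordinates convert back to 0-based BED starts", {
  ann <- tinyAnnotation()
  gr <- annExons(ann)["eA1"]
  gr$domain_name <- "d"
  path <- tempfile()
  writeDomainTable(gr, path)
  fields <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(fields[2]), GenomicRanges::start(gr) - 1L)
  expect_equal(as.integer(fields[3]), GenomicRanges::end(gr))
})

test_that("BED peak reader handles counts, empty files and bad intervals", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tRBP1_K562_rep1\t0\t+",
               "chr1\t300\t400\tRBP1_K562_rep1\t0\t+",
               "chr2\t10\t20\tRBP1_K562_rep1\t0\t-"), bed)
  ps <- readBedPeaks(bed)
  expect_equal(length(peakRanges(ps)), 3L)
  expect_equal(ps@rbp_name, "RBP1")
  expect_equal(GenomicRanges::start(peakRanges(ps))[1], 101L)  # 0-based in

  writeLines(character(0), bed)
  expect_equal(length(peakRanges(readBedPeaks(bed))), 0L)

  writeLines("chr1\t100\t100", bed)
  expect_error(readBedPeaks(bed), "line 1")
})

test_that("extractWindow follows transcription orientation and truncates", {
  g <- tinyGenome()          # ACGTACGT... (A at 1-based positions 1,5,9,...)
  ## plus-strand acceptor at 0-based exon start 100: bases [96,100) 0-based
  ## = 1-based 97..100 = ACGT
  w <- extractWindow(g, "chr1", 100, 4, side = "up", strand = "+")
  expect_equal(as.character(w), "ACGT")
  ## minus-strand acceptor at 0-based exon end 200: revcomp of 1-based
  ## 201..204 = revcomp(ACGT) = ACGT (palindrome)
  wm <- extractWindow(g, "chr1", 200, 4, side = "up", strand = "-")
  expect_equal(as.character(wm), "ACGT")
  ## palindromic window: identical for both strands
  wp <- extractWindow(g, "chr1", 100, 4, side = "down", strand = "+")
  wn <- extractWindow(g, "chr1", 104, 4, side = "up", strand = "-")
  expect_equal(as.character(wp), as.character(wn))
  ## truncation at the chromosome edge
  expect_warning(wt <- extractWindow(g, "chr1", 2, 10, side = "up",
                                     strand = "+"), "truncated")
  expect_equal(nchar(wt), 2L)
  expect_true(attr(wt, "truncated"))
  expect_error(extractWindow(g, "chrX", 100, 4, "up", "+"), "chrX")
})

test_that("gene bodies span min exon start to max exon end", {
  ann <- tinyAnnotation()
  gb <- geneBodyIntervals(ann)
  expect_equal(length(gb), 2L)
  expect_equal(GenomicRanges::start(gb["geneA"]), 101)
  expect_equal(GenomicRanges::end(gb["geneA"]), 800)
  ## single-transcript gene body equals its exon span
  expect_equal(GenomicRanges::start(gb["geneB"]), 101)
  expect_equal(GenomicRanges::end(gb["geneB"]), 600)
})

test_that("GMT, MEME and domain round trips preserve content", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g9"))
  path <- tempfile(fileext = ".gmt")
  writeGmt(sets, path, collection = "test")
  back <- readGmt(path)
  expect_equal(back$SET_A, sets$SET_A)
  expect_equal(attr(back, "collection"), c("test", "test"))

  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.7, 0.1, 0.1,
                0.1, 0.1, 0.1, 0.7,
                0.25, 0.25, 0.25, 0.25), 4)
  pw <- PWMotif(m, "M9", "RBPQ")
  mpath <- tempfile(fileext = ".meme")
  writeMemeMotifs(list(pw), mpath)
  back <- readMemeMotifs(mpath)
  expect_equal(back[[1]]@motif_id, "M9")
  expect_equal(pwmMatrix(back[[1]]), pwmMatrix(pw), tolerance = 1e-5)
  expect_equal(pwmConsensus(pw), "ACTA")

  dom <- GenomicRanges::GRanges("chr3", IRanges::IRanges(51, 120))
  dom$domain_name <- "PF1"
  dpath <- tempfile()
  writeDomainTable(dom, dpath)
  dback <- readDomainTable(dpath)
  expect_equal(GenomicRanges::start(dback), 51)
  writeLines("chr3\t70\t70\tPF1", dpath)
  expect_error(readDomainTable(dpath), "start >= end")
})
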