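test_that("specific exon sets are the per-side set differences", {
  ann <- tinyAnnotation()
  ## geneA.1 has {eA1..eA4}, geneA.2 has {eA1, eA3}: set1 = {eA2, eA4}
  pair <- deriveSpecificExons("geneA.1", "geneA.2", ann, "fetal", "adult")
  expect_setequal(pair$set1, c("eA2", "eA4"))
  expect_equal(pair$set2, character(0))
  ## identical exon sets on both sides: both empty
  pair2 <- deriveSpecificExons("geneA.2", "geneA.2", ann)
  expect_equal(length(pair2$set1), 0L)
  ## a gene with a specific isoform on only one side is excluded entirely
  pair3 <- deriveSpecificExons("geneA.1", "geneB.1", ann)
  expect_equal(length(pair3$set1), 0L)
  expect_equal(length(pair3$set2), 0L)
  expect_error(exonSetPair(c("e1"), c("e1"), "a", "b"), "disjoint")
})

test_that("domain overlap uses >= 1 bp intersection and Fisher", {
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(seq(1, 40 * 50, 50),
                                                width = 40))
  names(ex) <- sprintf("e%02d", 1:40)
  pair <- exonSetPair(names(ex)[1:20], names(ex)[21:40], "t1", "t2")
  ## equal overlap fractions 12/20 vs 12/20: OR = 1
  dom <- c(ex[c(1:12, 21:32)])
  res <- domainOverlapTest(pair, ex, GenomicRanges::GRanges(
    GenomicRanges::seqnames(dom), IRanges::IRanges(
      GenomicRanges::start(dom), GenomicRanges::end(dom))))
  expect_equal(res$odds_ratio, 1, tolerance = 1e-9)
  ## 18/20 vs 6/20 matches the enumeration oracle
  dom2 <- ex[c(1:18, 21:26)]
  res2 <- domainOverlapTest(pair, ex, GenomicRanges::granges(dom2))
  o <- fisherOracle(18, 2, 6, 14)
  expect_equal(res2$odds_ratio, o$or, tolerance = 1e-4)
  expect_equal(res2$p, o$p, tolerance = 1e-10)
  expect_true(res2$conf_int[1] <= res2$odds_ratio,
              res2$odds_ratio <= res2$conf_int[2])
  ## a single shared bp counts as overlap (both 1-based closed)
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(40, 45))
  res3 <- domainOverlapTest(exonSetPair("e01", "e02", "a", "b"), ex, one)
  expect_equal(res3$table[1, 1], 1L)     # e01 = [1,40] touches at 40
  expect_equal(res3$table[2, 1], 0L)     # e02 = [51,90] misses [40,45]
  expect_true(is.list(domainOverlapTest(exonSetPair(character(0), "e02",
                                                    "a", "b"), ex, one)))
})

test_that("splice windows honor coordinates and strand", {
  ## genome with distinguishable flanks around a [201, 300] exon
  s <- paste(c(rep("A", 100), rep("C", 100), rep("G", 100), rep("T", 100),
               rep("A", 100)), collapse = "")
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  exPlus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300),
                                   strand = "+")
  exMinus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300),
                                    strand = "-")
  names(exPlus) <- "p"; names(exMinus) <- "m"
  both <- c(exPlus, exMinus)
  pair <- exonSetPair("p", "m", "t1", "t2")
  prof <- spliceProfiles(pair, both, genome)
  ## plus acceptor window = [101, 200] = all C
  expect_equal(unname(prof$set1$acceptor["C", ]), rep(1L, 100))
  ## plus donor window = [301, 400] = all T
  expect_equal(unname(prof$set1$donor["T", ]), rep(1L, 100))
  ## minus acceptor window = revcomp of [301, 400] (T) = all A
  expect_equal(unname(prof$set2$acceptor["A", ]), rep(1L, 100))
  ## minus donor window = revcomp of [101, 200] (C) = all G
  expect_equal(unname(prof$set2$donor["G", ]), rep(1L, 100))
  ## conservation: counts per position sum to the set size
  expect_true(all(colSums(prof$set1$acceptor) == 1))
})

test_that("profiles are invariant under genome reverse-complementation", {
  ss <- simulateSpliceSets(c(30, 30), seed = 17)
  prof <- spliceProfiles(ss$pair, ss$exons, ss$genome)
  ## flip: reverse-complement the chromosome and mirror all coordinates
  L <- Biostrings::width(ss$genome)[[1]]
  rcGenome <- Biostrings::reverseComplement(ss$genome)
  names(rcGenome) <- names(ss$genome)
  ex <- ss$exons
  flipped <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex),
    IRanges::IRanges(L - GenomicRanges::end(ex) + 1,
                     L - GenomicRanges::start(ex) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(ex)) == "+",
                    "-", "+"))
  names(flipped) <- names(ex)
  prof2 <- spliceProfiles(ss$pair, flipped, rcGenome)
  expect_identical(prof$set1, prof2$set1)
  expect_identical(prof$set2, prof2$set2)
})

test_that("positional tests match the enumeration oracle and flag plants", {
  ## constructed 2x2: (380, 20 / 280, 120) at donor +1
  prof <- list(
    set1 = list(acceptor = matrix(0L, 4, 0, dimnames =
                                    list(c("A", "C", "G", "T"), NULL)),
                donor = matrix(c(5L, 5L, 380L, 10L), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), "1"))),
    set2 = list(acceptor = matrix(0L, 4, 0, dimnames =
                                    list(c("A", "C", "G", "T"), NULL)),
                donor = matrix(c(40L, 40L, 280L, 40L), 4, 1,
                               dimnames = list(c("A", "C", "G", "T"), "1"))))
  class(prof) <- "SpliceSiteProfiles"
  res <- positionalTests(prof, sides = "donor")
  g <- res[res$nucleotide == "G", ]
  o <- fisherOracle(380, 20, 280, 120)
  expect_equal(g$odds_ratio, o$or, tolerance = 1e-4)
  expect_equal(g$p, o$p, tolerance = 1e-10)
  expect_true(g$most_common)
  ## identical composition: OR 1, p 1 throughout
  prof$set2 <- prof$set1
  res2 <- positionalTests(prof, sides = "donor")
  expect_true(all(res2$p == 1))
  expect_true(all(abs(res2$odds_ratio[is.finite(res2$odds_ratio)] - 1) <
                    1e-9 | res2$count1 == 0))
})

test_that("polypyrimidine fractions are additive and tests detect T shifts", {
  ss <- simulateSpliceSets(
    c(300, 300),
    list(spliceSetProfile(ppt_t = 0.6), spliceSetProfile(ppt_t = 0.4)),
    seed = 23)
  prof <- spliceProfiles(ss$pair, ss$exons, ss$genome)
  ppt <- polypyrimidineProfile(prof)
  expect_equal(ppt$table$py_frac1,
               ppt$table$t_frac1 +
                 prof$set1$acceptor["C", ] / colSums(prof$set1$acceptor),
               tolerance = 1e-12, ignore_attr = TRUE)
  ## the tract positions (-25..-5) are planted at 0.6 vs 0.4
  tract <- ppt$table$position %in% -25:-5
  expect_gt(sum(ppt$table$p_adj[tract] < 0.05), 15)
  expect_equal(ppt$n_sig_set2, 0)
})

test_that("motif containment scores the consensus and null sets stay flat", {
  m <- matrix(0.05, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("T", "G", "C", "A", "T", "G")
  for (j in 1:6) m[cons[j], j] <- 0.85
  pw <- PWMotif(m, "M1", "RBPX")
  lo <- log2(pmax(m, 0.01) / 0.25)
  thr <- 0.8 * sum(apply(lo, 2, max))
  win <- paste0(strrep("A", 40), "TGCATG", strrep("A", 54))
  expect_gte(cardiosplice:::.pwmMaxScore(win, lo), thr)
  expect_lt(cardiosplice:::.pwmMaxScore(strrep("A", 100), lo), thr)

  ## identical window sets give log2 ratio 0 and q ~ 1
  ss <- simulateSpliceSets(c(40, 40), seed = 31)
  ann <- new("TranscriptAnnotation",
             genes = data.frame(gene_id = "g", gene_name = "g",
                                strand = "+", row.names = "g"),
             transcripts = list(t1 = c("dummy", names(ss$exons))),
             txGene = c(t1 = "g"), exons = c(
               GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 10),
                                      strand = "+", seqinfo = NULL) |>
                 setNames("dummy"), ss$exons))
  res <- motifWindowEnrichment(ss$pair, ann, ss$genome, list(pw))
  expect_s3_class(res, "data.frame")
  expect_lt(abs(res$log2_ratio), 1.5)   # no planted difference
  expect_gt(res$q, 0.05)
  ## PWM longer than the window is skipped with a warning
  long <- PWMotif(matrix(0.25, 4, 120,
                         dimnames = list(c("A", "C", "G", "T"), NULL)),
                  "LONG", "R")
  expect_warning(res2 <- motifWindowEnrichment(ss$pair, ann, ss$genome,
                                               list(long)), "skipped")
  expect_null(res2)
})
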