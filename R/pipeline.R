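## Configuration-driven orchestration of all stages on a synthetic cohort,
## with TSV outputs, JSON provenance sidecars and a manifest. Reruns with
## the same configuration are byte-identical.

.knownConfigKeys <- c("seed", "outdir", "stages", "synthetic", "thresholds",
                      "deconv_method")
.allStages <- c("simulate", "preprocess", "de", "deconvolute", "ridge",
                "exons", "eclip", "heartfailure")

#' Validate a pipeline configuration
#'
#' Accepts a YAML path or a list. Unknown top-level keys, unknown stages and
#' out-of-range thresholds fail before any stage runs; defaults are filled
#' in for everything else.
#'
#' @param config list or path to a YAML file.
#' @return validated, fully populated configuration list.
#' @export
validatePipelineConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .knownConfigKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- list(
    seed = config$seed %||% 1L,
    outdir = config$outdir %||% "pipeline_out",
    stages = config$stages %||% .allStages,
    synthetic = config$synthetic %||% list(),
    thresholds = config$thresholds %||% list(),
    deconv_method = config$deconv_method %||% "nusvr")
  badStage <- setdiff(cfg$stages, .allStages)
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  th <- cfg$thresholds
  cfg$thresholds <- list(
    alpha = th$alpha %||% 0.05,
    lr_thresh = th$lr_thresh %||% 2,
    min_tpm = th$min_tpm %||% 1,
    min_usage = th$min_usage %||% 0.10,
    min_frac = th$min_frac %||% 0.10,
    K = th$K %||% 10,
    eclip_grid = th$eclip_grid %||% seq(0, 6, by = 0.5))
  with(cfg$thresholds, stopifnot(
    alpha > 0, alpha < 1, lr_thresh >= 0, min_tpm >= 0,
    min_usage >= 0, min_usage < 1, min_frac > 0, min_frac <= 1, K >= 1))
  if (!cfg$deconv_method %in% c("nusvr", "nnls"))
    stop("deconv_method must be 'nusvr' or 'nnls'")
  cfg
}

.writeArtifact <- function(df, path, stage, confHash, seed) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(stage = stage, config_hash = confHash, seed = seed,
         n_rows = nrow(df),
         package = as.character(utils::packageVersion("cardiosplice"))),
    side, auto_unbox = TRUE)
  c(path, side)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the stages in dependency order (simulate, preprocess, DE,
#' deconvolution, ridge DE, exon analyses, eCLIP sweep, heart failure),
#' writing every result as a TSV with a JSON provenance sidecar (stage,
#' configuration hash, seed). Stage inputs come from earlier stages held in
#' memory; rerunning with the same configuration reproduces every output
#' byte-identically.
#'
#' @param config list or YAML path (see
#'   \code{\link{validatePipelineConfig}}).
#' @return list: \code{manifest} (data.frame stage/path), \code{results}
#'   (in-memory stage results), \code{config}.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validatePipelineConfig(config)
  th <- cfg$thresholds
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  confHash <- rlang::hash(cfg[setdiff(names(cfg), "outdir")])
  manifest <- list()
  add <- function(stage, paths)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, path = paths, stringsAsFactors = FALSE)
  emit <- function(df, name, stage)
    add(stage, .writeArtifact(df, file.path(cfg$outdir, name), stage,
                              confHash, cfg$seed))
  res <- list()

  ## simulate ---------------------------------------------------------------
  simArgs <- cfg$synthetic
  simArgs$seed <- cfg$seed
  sc <- do.call(simConfig, simArgs)
  cohort <- simulateCohort(sc)
  res$cohort <- cohort
  if ("simulate" %in% cfg$stages) {
    emit(cohort$samples, "samples.tsv", "simulate")
    p1 <- file.path(cfg$outdir, "gene_tpm.tsv")
    writeFeatureMatrix(cohort$gene_tpm, p1); add("simulate", p1)
    p2 <- file.path(cfg$outdir, "isoform_tpm.tsv")
    writeFeatureMatrix(cohort$iso_tpm, p2); add("simulate", p2)
    p3 <- file.path(cfg$outdir, "annotation.gtf")
    writeGtfAnnotation(cohort$annotation, p3); add("simulate", p3)
    p4 <- file.path(cfg$outdir, "genome.fa")
    Biostrings::writeXStringSet(cohort$genome, p4); add("simulate", p4)
  }

  ## preprocess -------------------------------------------------------------
  gf <- filterExpressedGenes(cohort$gene_tpm, th$min_tpm, th$min_frac)
  usage <- computeIsoformUsage(cohort$iso_tpm, cohort$annotation)
  uf <- filterExpressedIsoforms(usage, cohort$annotation, th$min_usage,
                                th$min_frac)
  geneNorm <- inverseNormalTransform(gf$matrix)
  isoNorm <- inverseNormalTransform(uf$matrix)
  res$preprocess <- list(gene_filter = gf$report, iso_filter = uf$report,
                         gene_norm = geneNorm, iso_norm = isoNorm,
                         usage = uf$matrix)
  if ("preprocess" %in% cfg$stages) {
    message(sprintf("[preprocess] genes %d -> %d; isoforms %d -> %d",
                    gf$report$n_input, gf$report$n_expressed,
                    uf$report$n_input, uf$report$n_expressed))
    emit(data.frame(step = c("genes", "isoforms"),
                    n_input = c(gf$report$n_input, uf$report$n_input),
                    n_expressed = c(gf$report$n_expressed,
                                    uf$report$n_expressed),
                    criterion = c(gf$report$criterion, uf$report$criterion)),
         "filter_report.tsv", "preprocess")
    pg <- file.path(cfg$outdir, "gene_normalized.tsv")
    writeFeatureMatrix(geneNorm, pg); add("preprocess", pg)
  }

  samples <- cohort$samples
  healthy <- samples[!samples$tissue %in% c("HF_pre", "HF_post"), ]

  ## pairwise DE ------------------------------------------------------------
  pairs <- list(c("iPSC-CVPC", "adult_heart"),
                c("iPSC-CVPC", "adult_arteria"),
                c("adult_heart", "adult_arteria"))
  res$de_genes <- list(); res$de_isoforms <- list()
  for (pp in pairs) {
    key <- paste(pp, collapse = "_vs_")
    dg <- fitLinearDE(geneNorm, healthy, pp[1], pp[2])
    dg <- classifySpecific(dg, gf$matrix, healthy, pp[1], pp[2],
                           th$lr_thresh, th$alpha)
    di <- fitLinearDE(isoNorm, healthy, pp[1], pp[2])
    di <- classifySpecific(di, uf$matrix, healthy, pp[1], pp[2],
                           th$lr_thresh, th$alpha)
    res$de_genes[[key]] <- dg
    res$de_isoforms[[key]] <- di
    if ("de" %in% cfg$stages) {
      emit(dg, sprintf("de_genes_%s.tsv", key), "de")
      emit(di, sprintf("de_isoforms_%s.tsv", key), "de")
    }
  }

  ## deconvolution ----------------------------------------------------------
  markers <- findMarkers(cohort$sc_counts, cohort$sc_labels)
  sig <- buildSignature(cohort$sc_counts, cohort$sc_labels, markers)
  est <- estimateProportions(cohort$gene_tpm[rownames(sig), ], sig,
                             method = cfg$deconv_method)
  res$deconvolution <- list(markers = markers, signature = sig,
                            proportions = est$proportions,
                            diagnostics = est$diagnostics)
  if ("deconvolute" %in% cfg$stages) {
    emit(markers, "markers.tsv", "deconvolute")
    emit(data.frame(gene_id = rownames(sig), sig, check.names = FALSE),
         "signature.tsv", "deconvolute")
    emit(data.frame(sample_id = rownames(est$proportions), est$proportions,
                    check.names = FALSE),
         "proportions.tsv", "deconvolute")
  }

  ## ridge DE with proportions ----------------------------------------------
  if ("ridge" %in% cfg$stages) {
    rg <- fitRidgeDE(geneNorm, healthy, "iPSC-CVPC", "adult_heart",
                     est$proportions)
    res$ridge_genes <- rg
    emit(rg, "ridge_genes_iPSC-CVPC_vs_adult_heart.tsv", "ridge")
    ri <- fitRidgeDE(isoNorm, healthy, "iPSC-CVPC", "adult_heart",
                     est$proportions)
    res$ridge_isoforms <- ri
    emit(ri, "ridge_isoforms_iPSC-CVPC_vs_adult_heart.tsv", "ridge")
  }

  ## exon analyses ----------------------------------------------------------
  di <- res$de_isoforms[["iPSC-CVPC_vs_adult_heart"]]
  spec1 <- di$feature_id[di$class == "tissue1_specific"]
  spec2 <- di$feature_id[di$class == "tissue2_specific"]
  pair <- deriveSpecificExons(spec1, spec2, cohort$annotation,
                              "iPSC-CVPC", "adult_heart")
  res$exon_pair <- pair
  if ("exons" %in% cfg$stages && length(pair$set1) && length(pair$set2)) {
    dom <- domainOverlapTest(pair, annExons(cohort$annotation),
                             cohort$domains)
    res$domain_test <- dom
    profiles <- spliceProfiles(pair, annExons(cohort$annotation),
                               cohort$genome)
    pt <- positionalTests(profiles)
    ppt <- polypyrimidineProfile(profiles)
    mot <- motifWindowEnrichment(pair, cohort$annotation, cohort$genome,
                                 cohort$motifs)
    res$positional <- pt; res$polypyrimidine <- ppt; res$motifs <- mot
    emit(pt, "splice_positional_tests.tsv", "exons")
    emit(ppt$table, "polypyrimidine.tsv", "exons")
    emit(mot, "motif_enrichment.tsv", "exons")
    emit(data.frame(odds_ratio = dom$odds_ratio, p = dom$p,
                    n_set1 = length(pair$set1), n_set2 = length(pair$set2)),
         "domain_overlap.tsv", "exons")
  }

  ## eCLIP sweep ------------------------------------------------------------
  if ("eclip" %in% cfg$stages) {
    bodies <- geneBodyIntervals(cohort$annotation)
    sweep <- thresholdSweep(di, txToGene(cohort$annotation), bodies,
                            cohort$peaks, th$eclip_grid, th$alpha)
    res$eclip <- sweep
    emit(sweep$curves, "eclip_curves.tsv", "eclip")
    emit(sweep$mean_curve, "eclip_mean_curve.tsv", "eclip")
  }

  ## heart failure ----------------------------------------------------------
  if ("heartfailure" %in% cfg$stages) {
    rbp <- cohort$truth$rbp_genes
    pca <- jointRbpPca(cohort$gene_tpm, rbp)
    dist <- groupDistances(pca$scores, samples, K = th$K)
    hfSamples <- samples[samples$tissue %in% c("HF_pre", "adult_heart"), ]
    hfIso <- fitRidgeDE(
      inverseNormalTransform(uf$matrix[, hfSamples$sample_id]),
      hfSamples, "HF_pre", "adult_heart", est$proportions,
      coef_names = "tissue")
    hfGene <- fitRidgeDE(
      inverseNormalTransform(gf$matrix[, hfSamples$sample_id]),
      hfSamples, "HF_pre", "adult_heart", est$proportions,
      coef_names = "tissue")
    rbpEff <- hfGene$effect[hfGene$feature_id %in% rbp]
    loc <- rbpEffectSizeLocationTest(rbpEff)
    fetalIso <- res$ridge_isoforms
    if (is.null(fetalIso))
      fetalIso <- fitRidgeDE(isoNorm, healthy, "iPSC-CVPC", "adult_heart",
                             est$proportions, coef_names = "tissue")
    rev <- reversionStatistic(
      hfIso[hfIso$coefficient == "tissue", ],
      fetalIso[fetalIso$coefficient == "tissue", ], th$alpha)
    res$heartfailure <- list(pca = pca, distances = dist,
                             rbp_location = loc, reversion = rev)
    emit(data.frame(sample_id = rownames(pca$scores),
                    pca$scores[, seq_len(min(10, ncol(pca$scores)))],
                    check.names = FALSE),
         "rbp_pca_scores.tsv", "heartfailure")
    emit(dist$distances, "hf_distances.tsv", "heartfailure")
    emit(dist$paired_tests, "hf_distance_tests.tsv", "heartfailure")
    emit(data.frame(A = rev$counts["A"], B = rev$counts["B"],
                    C = rev$counts["C"], D = rev$counts["D"],
                    odds_ratio = rev$odds_ratio, p = rev$p, r = rev$r),
         "reversion.tsv", "heartfailure")
  }

  list(manifest = do.call(rbind, manifest), results = res, config = cfg)
}
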