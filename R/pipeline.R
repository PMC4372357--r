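## End-to-end orchestration: map -> evidence -> score -> chromatin ->
## drugs, with a reproducibility manifest.

.overlapTestAsList <- function(ot)
  list(universe_n = ot@universeN, category_k = ot@categoryK,
       draw_n = ot@drawN, overlap_k = ot@overlapK,
       expected = ot@expected, fold = ot@fold, p_upper = ot@pUpper)

#' Serialize a drug-overlap report to a plain list / JSON
#'
#' @param report A [DrugOverlapReport-class].
#' @return Nested list mirroring the report's slots (connection paths
#'   excluded; they are tabular and written separately).
#' @export
drugReportAsList <- function(report)
  list(n_seed_genes = length(report@seedGenes),
       n_x = length(report@xSet),
       crc_test = .overlapTestAsList(report@crcTest),
       all_test = .overlapTestAsList(report@allTest),
       relative_fold = report@relativeFold,
       comparison_p = report@comparisonP,
       n_connections = nrow(report@connections))

#' Run the full prioritization pipeline on a bundle directory
#'
#' Executes the stages in order — candidate mapping, evidence matrix,
#' scoring, per-cell-type chromatin permutation scan, drug-target
#' overlap — and writes the stage tables (TSV), the drug report and
#' score summary (JSON), and a run manifest with the config snapshot,
#' input file digests, seed and stage timings. The manifest is written
#' last, atomically; a failed run removes its partial outputs. Re-running
#' with the same bundle, config and seed reproduces identical outputs.
#'
#' @param bundleDir Bundle directory ([writeBundle()] layout).
#' @param outDir Output directory (created; may pre-exist).
#' @param cfg A [PipelineConfig-class]; alternatively set `configPath`.
#' @param configPath Optional YAML config ([readPipelineConfig()]);
#'   ignored when `cfg` is given.
#' @return The manifest, invisibly (list).
#' @export
runPipeline <- function(bundleDir, outDir, cfg = NULL, configPath = NULL) {
  if (is.null(cfg))
    cfg <- if (!is.null(configPath)) readPipelineConfig(configPath)
           else pipelineConfig()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  out <- function(name) {
    p <- file.path(outDir, name)
    written <<- c(written, p)
    p
  }
  timings <- list()
  stage <- function(name, expr) {
    message(sprintf("[snp2drug] stage %s ...", name))
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  tryCatch({
    bundle <- stage("load", readBundle(bundleDir))
    pairs <- stage("map", mapAllLoci(bundle, cfg))
    writeTsv(pairs, out("candidates.tsv"))
    ev <- stage("evidence", buildEvidenceMatrix(pairs, bundle, cfg))
    writeTsv(ev, out("evidence.tsv"))
    scored <- stage("score", scoreRows(ev, cfg@scoreThreshold))
    writeTsv(scored, out("scores.tsv"))
    jsonlite::write_json(scoreSummary(scored, cfg@scoreThreshold),
                         out("score_summary.json"), auto_unbox = TRUE)
    chrom <- stage("chromatin", multiCelltypeScan(
      lociPositions(bundle, cfg), bundle@snpUniverse, bundle@peaks, cfg))
    writeTsv(chrom, out("chromatin.tsv"))
    jsonlite::write_json(chrom, out("chromatin.json"), digits = NA)
    drug <- stage("drugs", drugOverlapReport(
      scored, bundle@network, bundle@drugs, bundle@geneUniverseN, cfg))
    jsonlite::write_json(drugReportAsList(drug), out("drug_report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeTsv(connectionPaths(drug), out("connections.tsv"))

    digests <- tools::md5sum(list.files(bundleDir, recursive = TRUE,
                                        full.names = TRUE))
    names(digests) <- sub(paste0("^", bundleDir, "/?"), "",
                          names(digests))
    manifest <- list(
      config = yaml::yaml.load(yaml::as.yaml(list(
        r2_threshold = cfg@r2Threshold, eqtl_fdr_max = cfg@eqtlFdrMax,
        eqtl_p_max = cfg@eqtlPMax, eqtl_cis_window = cfg@eqtlCisWindow,
        gene_p_threshold = cfg@genePThreshold,
        category_p_threshold = cfg@categoryPThreshold,
        score_threshold = cfg@scoreThreshold,
        permutation_iters = cfg@permutationIters,
        rng_seed = cfg@rngSeed, locus_flank_bp = cfg@locusFlankBp,
        ease_adjust = cfg@easeAdjust,
        match_locus_size = cfg@matchLocusSize))),
      seed = cfg@rngSeed,
      input_digests = as.list(digests),
      stage_seconds = timings,
      outputs = basename(written))
    tmp <- tempfile(tmpdir = outDir)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, file.path(outDir, "manifest.json"))
    invisible(manifest)
  }, error = function(e) {
    unlink(written)
    stopf("pipeline failed (partial outputs removed): %s",
          conditionMessage(e))
  })
}
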