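## Central S4 containers: run configuration, the resource bundle feeding the
## pipeline, the exact overlap test, and the drug-overlap report.

setClassUnion("df_OR_NULL", c("data.frame", "NULL"))

#' Pipeline configuration
#'
#' Holds every tunable threshold of the prioritization pipeline. Defaults
#' encode the pipeline's operating point: LD proxies qualify at r-squared
#' strictly above 0.80; cis-eQTL support requires FDR below 0.50, p below
#' 0.0016 and a SNP-probe distance under 250 kb; per-gene p-value criteria
#' and category enrichment use p < 0.05; genes scoring at least 2 of the 7
#' criteria are called biological risk genes; chromatin permutation tests
#' run 1e5 iterations.
#'
#' All significance thresholds are strict ("<"); boundary values fail.
#'
#' @slot r2Threshold LD r-squared cut-off (proxies must exceed it).
#' @slot eqtlFdrMax,eqtlPMax,eqtlCisWindow cis-eQTL qualification bounds
#'   (FDR, p, SNP-probe distance in bp).
#' @slot genePThreshold p cut-off for the text-mining and PPI-seed gene
#'   p-value criteria.
#' @slot categoryPThreshold p cut-off for category enrichment (criteria 6-7).
#' @slot scoreThreshold minimum criterion count for a biological risk gene.
#' @slot permutationIters iterations of the peak-overlap permutation test.
#' @slot rngSeed global seed; stage seeds are derived via [deriveSeed()].
#' @slot locusFlankBp symmetric flank added to each LD interval, bp.
#' @slot easeAdjust use the conservative EASE-style tail (overlap minus one)
#'   for category enrichment instead of the plain hypergeometric tail.
#' @slot matchLocusSize permutation null samples as many positions per locus
#'   as the observed locus has member SNPs, instead of one.
#' @export
setClass("PipelineConfig", representation(
  r2Threshold = "numeric", eqtlFdrMax = "numeric", eqtlPMax = "numeric",
  eqtlCisWindow = "numeric", genePThreshold = "numeric",
  categoryPThreshold = "numeric", scoreThreshold = "integer",
  permutationIters = "integer", rngSeed = "integer",
  locusFlankBp = "integer", easeAdjust = "logical",
  matchLocusSize = "logical"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  inUnit <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!inUnit(object@r2Threshold)) msg <- c(msg, "r2Threshold must be in [0,1]")
  if (!inUnit(object@eqtlFdrMax)) msg <- c(msg, "eqtlFdrMax must be in [0,1]")
  if (!inUnit(object@eqtlPMax)) msg <- c(msg, "eqtlPMax must be in [0,1]")
  if (!inUnit(object@genePThreshold)) msg <- c(msg, "genePThreshold must be in [0,1]")
  if (!inUnit(object@categoryPThreshold)) msg <- c(msg, "categoryPThreshold must be in [0,1]")
  if (object@eqtlCisWindow <= 0) msg <- c(msg, "eqtlCisWindow must be positive")
  if (object@scoreThreshold < 0L) msg <- c(msg, "scoreThreshold must be >= 0")
  if (object@permutationIters < 1L) msg <- c(msg, "permutationIters must be >= 1")
  if (object@locusFlankBp < 0L) msg <- c(msg, "locusFlankBp must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PipelineConfig-class
#' @param r2Threshold,eqtlFdrMax,eqtlPMax,eqtlCisWindow,genePThreshold
#'   numeric thresholds, see slots.
#' @param categoryPThreshold,scoreThreshold,permutationIters,rngSeed,locusFlankBp
#'   further settings, see slots.
#' @param easeAdjust,matchLocusSize logical switches, see slots.
#' @return `pipelineConfig()` returns a validated `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(rngSeed = 1L)
#' cfg
#' @export
pipelineConfig <- function(r2Threshold = 0.80, eqtlFdrMax = 0.50,
                           eqtlPMax = 0.0016, eqtlCisWindow = 250000,
                           genePThreshold = 0.05, categoryPThreshold = 0.05,
                           scoreThreshold = 2L, permutationIters = 100000L,
                           rngSeed = 1L, locusFlankBp = 0L,
                           easeAdjust = FALSE, matchLocusSize = FALSE) {
  new("PipelineConfig",
      r2Threshold = as.numeric(r2Threshold),
      eqtlFdrMax = as.numeric(eqtlFdrMax), eqtlPMax = as.numeric(eqtlPMax),
      eqtlCisWindow = as.numeric(eqtlCisWindow),
      genePThreshold = as.numeric(genePThreshold),
      categoryPThreshold = as.numeric(categoryPThreshold),
      scoreThreshold = as.integer(scoreThreshold),
      permutationIters = as.integer(permutationIters),
      rngSeed = as.integer(rngSeed), locusFlankBp = as.integer(locusFlankBp),
      easeAdjust = isTRUE(easeAdjust), matchLocusSize = isTRUE(matchLocusSize))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n",
      sprintf("  LD r2 > %.2f, flank %d bp\n", object@r2Threshold,
              object@locusFlankBp),
      sprintf("  eQTL: FDR < %.2f, p < %g, cis window < %d bp\n",
              object@eqtlFdrMax, object@eqtlPMax,
              as.integer(object@eqtlCisWindow)),
      sprintf("  gene p < %g; category p < %g%s\n", object@genePThreshold,
              object@categoryPThreshold,
              if (object@easeAdjust) " (EASE tail)" else ""),
      sprintf("  biological score >= %d; permutation %d iters; seed %d\n",
              object@scoreThreshold, object@permutationIters, object@rngSeed),
      sep = "")
})

#' Exact hypergeometric overlap test
#'
#' The package's shared enrichment statistic: drawing `drawN` genes from a
#' universe of `universeN` of which `categoryK` belong to the category, what
#' is the chance of an overlap at least as large as the `overlapK` observed?
#' `expected` is K*n/N, `fold` is k/expected, and `pUpper` is the exact
#' upper tail P(X >= k) computed in log space (see
#' [hypergeomUpperTail()]).
#'
#' @slot universeN,categoryK,drawN,overlapK the (N, K, n, k) counts.
#' @slot expected,fold,pUpper derived statistics.
#' @seealso [overlapTest()], [overlapTestCounts()]
#' @export
setClass("OverlapTest", representation(
  universeN = "integer", categoryK = "integer", drawN = "integer",
  overlapK = "integer", expected = "numeric", fold = "numeric",
  pUpper = "numeric"))

setValidity("OverlapTest", function(object) {
  msg <- character()
  N <- object@universeN; K <- object@categoryK
  n <- object@drawN; k <- object@overlapK
  if (K > N || n > N) msg <- c(msg, "category and draw must fit in the universe")
  if (k < 0L || k > min(K, n)) msg <- c(msg, "overlap k must satisfy 0 <= k <= min(K, n)")
  if (length(object@pUpper) == 1L && is.finite(object@pUpper) &&
      (object@pUpper <= 0 || object@pUpper > 1))
    msg <- c(msg, "pUpper must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf(
    "OverlapTest: k = %d of K = %d in draw n = %d from N = %d\n  expected %.4g, fold %.4g, upper-tail p %.4g\n",
    object@overlapK, object@categoryK, object@drawN, object@universeN,
    object@expected, object@fold, object@pUpper))
})

#' Drug-target overlap report
#'
#' Result of the drug-repositioning stage: the expanded gene set x
#' (biological risk genes plus their one-hop protein-interaction
#' neighbours), its exact overlap tests against the approved disease-drug
#' target set y and the all-drug target set z, the relative fold
#' (k_y/K_y)/(k_z/K_z), a Fisher comparison p of the two target sets, and
#' the flat SNP - risk gene - interacting gene - drug connection table.
#'
#' @slot xSet character, the expanded gene set.
#' @slot seedGenes character, the biological risk genes used as seeds.
#' @slot crcTest,allTest [OverlapTest-class] against the disease-approved
#'   and all-drug target sets.
#' @slot relativeFold,comparisonP relative enrichment of the two target
#'   sets and its one-sided Fisher p (NA-flagged when undefined).
#' @slot connections data.frame with columns snp, risk_gene, ppi_gene,
#'   drug, indication.
#' @export
setClass("DrugOverlapReport", representation(
  xSet = "character", seedGenes = "character", crcTest = "OverlapTest",
  allTest = "OverlapTest", relativeFold = "numeric", comparisonP = "numeric",
  connections = "data.frame"))

setMethod("show", "DrugOverlapReport", function(object) {
  cat(sprintf("DrugOverlapReport: %d seed genes expanded to |x| = %d\n",
              length(object@seedGenes), length(object@xSet)))
  cat(sprintf("  approved disease drugs: %d/%d targets hit, fold %.4g, p %.4g\n",
              object@crcTest@overlapK, object@crcTest@categoryK,
              object@crcTest@fold, object@crcTest@pUpper))
  cat(sprintf("  all drugs:              %d/%d targets hit, fold %.4g, p %.4g\n",
              object@allTest@overlapK, object@allTest@categoryK,
              object@allTest@fold, object@allTest@pUpper))
  cat(sprintf("  relative fold %.4g (comparison p %.4g); %d connection paths\n",
              object@relativeFold, object@comparisonP,
              nrow(object@connections)))
})

#' Resource bundle: every table the pipeline consumes
#'
#' Aggregates the pre-computed inputs of the pipeline: the GWAS risk-SNP
#' table, LD proxies, gene models, variant consequences, cis-eQTL rows,
#' per-gene p-value tables standing in for text-mining and PPI-seed tools,
#' the somatic-mutation gene set, knockout-phenotype and functional-term
#' gene-set collections, per-cell-type chromatin peak sets, the SNP
#' universe for permutation, the PPI edge list, the drug-target table and
#' the gene-universe size N for hypergeometric tests.
#'
#' @slot riskSnps data.frame: rsid, chrom, pos, region, assoc_p,
#'   odds_ratio, ci_low, ci_high.
#' @slot ld data.frame: lead_rsid, proxy_rsid, r2, proxy_chrom, proxy_pos.
#' @slot genes [GenomicRanges::GRanges] with a `symbol` metadata column.
#' @slot consequences data.frame: rsid, gene, consequence.
#' @slot eqtl data.frame: rsid, gene, p, fdr, distance.
#' @slot textminingP,ppiSeedP named numeric: gene -> p.
#' @slot somaticGenes character set of symbols.
#' @slot koCategories,functionalTerms named lists of symbol sets.
#' @slot peaks named list of [GenomicRanges::GRanges], one per cell type.
#' @slot snpUniverse data.frame: chrom, pos (1-based).
#' @slot network data.frame: from, to (undirected, canonicalized).
#' @slot drugs data.frame: drug, target, status, indication, crc_approved.
#' @slot geneUniverseN integer, hypergeometric universe size; defaults to
#'   the PPI node count, which it may never undercut.
#' @export
setClass("ResourceBundle", representation(
  riskSnps = "data.frame", ld = "data.frame", genes = "ANY",
  consequences = "data.frame", eqtl = "data.frame",
  textminingP = "numeric", ppiSeedP = "numeric",
  somaticGenes = "character", koCategories = "list",
  functionalTerms = "list", peaks = "list", snpUniverse = "data.frame",
  network = "data.frame", drugs = "data.frame", geneUniverseN = "integer"))

setValidity("ResourceBundle", function(object) {
  msg <- character()
  nNodes <- length(unique(c(object@network$from, object@network$to)))
  if (length(object@geneUniverseN) != 1L || is.na(object@geneUniverseN))
    msg <- c(msg, "geneUniverseN must be a single integer")
  else if (object@geneUniverseN < nNodes)
    msg <- c(msg, sprintf("geneUniverseN (%d) below PPI node count (%d)",
                          object@geneUniverseN, nNodes))
  if (!is(object@genes, "GRanges"))
    msg <- c(msg, "genes must be a GRanges with a symbol column")
  else if (!"symbol" %in% names(S4Vectors::mcols(object@genes)))
    msg <- c(msg, "genes GRanges needs a 'symbol' metadata column")
  else if (anyDuplicated(S4Vectors::mcols(object@genes)$symbol))
    msg <- c(msg, "gene symbols must be unique after case normalization")
  if (length(object@peaks) && is.null(names(object@peaks)))
    msg <- c(msg, "peaks must be a named list (cell types)")
  if (nrow(object@ld) && (any(object@ld$r2 < 0) || any(object@ld$r2 > 1)))
    msg <- c(msg, "LD r2 must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ResourceBundle", function(object) {
  cat("ResourceBundle\n",
      sprintf("  %d risk SNPs, %d LD proxy rows, %d gene models\n",
              nrow(object@riskSnps), nrow(object@ld), length(object@genes)),
      sprintf("  %d consequence rows, %d eQTL rows, %d/%d gene p-values (text-mining/PPI)\n",
              nrow(object@consequences), nrow(object@eqtl),
              length(object@textminingP), length(object@ppiSeedP)),
      sprintf("  %d somatic genes, %d KO categories, %d functional terms\n",
              length(object@somaticGenes), length(object@koCategories),
              length(object@functionalTerms)),
      sprintf("  %d peak sets, %d universe SNPs, %d PPI edges, %d drug rows, N = %d\n",
              length(object@peaks), nrow(object@snpUniverse),
              nrow(object@network), nrow(object@drugs),
              object@geneUniverseN),
      sep = "")
})

#' Simulation configuration for synthetic resource bundles
#'
#' Parameters of the synthetic-data generator (see [simulateBundle()]).
#' Defaults emulate the study conditions the pipeline was designed around:
#' 50 risk loci over a ~2000-gene universe with about 2.8 candidate genes
#' per locus (~140 SNP-gene pairs), 35 planted high-evidence genes,
#' per-criterion background rates matching the reported per-criterion hit
#' counts out of 140, 34 chromatin cell types with one enriched, and a
#' drug table with 8 disease-approved targets among 150 total.
#'
#' @slot nGenes,nLoci,genesPerLocusMean gene universe and locus structure.
#' @slot criterionRates numeric length 7, background Bernoulli rate per
#'   criterion (missense, eqtl, textmining, ppi_seed, somatic,
#'   ko_phenotype, functional).
#' @slot plantedGenes,elevatedRate number of planted genes and their
#'   per-criterion success rate.
#' @slot ppiEdgeProb Erdos-Renyi edge probability of the background PPI.
#' @slot nDrugTargets,nCrcTargets,plantedLinkProb drug-target counts and
#'   the probability of a planted edge between a planted gene and a
#'   disease-approved target.
#' @slot peakCoverageBg,peakCoverageEnriched fraction of universe SNPs
#'   (background cell types) and of locus SNPs (the enriched cell type)
#'   covered by peaks.
#' @slot nCellTypes number of peak sets; the first is the enriched one.
#' @slot seed integer generator seed.
#' @export
setClass("SimulationConfig", representation(
  nGenes = "integer", nLoci = "integer", genesPerLocusMean = "numeric",
  criterionRates = "numeric", plantedGenes = "integer",
  elevatedRate = "numeric", ppiEdgeProb = "numeric",
  nDrugTargets = "integer", nCrcTargets = "integer",
  plantedLinkProb = "numeric", peakCoverageBg = "numeric",
  peakCoverageEnriched = "numeric", nCellTypes = "integer",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(object@criterionRates, object@elevatedRate, object@ppiEdgeProb,
             object@plantedLinkProb, object@peakCoverageBg,
             object@peakCoverageEnriched)
  if (any(probs < 0 | probs > 1)) msg <- c(msg, "all probabilities must be in [0,1]")
  if (length(object@criterionRates) != 7L)
    msg <- c(msg, "criterionRates must have length 7")
  if (object@plantedGenes > object@nGenes ||
      object@nDrugTargets > object@nGenes ||
      object@nCrcTargets > object@nDrugTargets)
    msg <- c(msg, "counts must not exceed nGenes (and CRC targets <= drug targets)")
  if (object@nLoci < 1L || object@nGenes < 1L || object@nCellTypes < 0L)
    msg <- c(msg, "nGenes, nLoci must be >= 1 and nCellTypes >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nGenes,nLoci,genesPerLocusMean,criterionRates,plantedGenes see slots.
#' @param elevatedRate,ppiEdgeProb,nDrugTargets,nCrcTargets see slots.
#' @param plantedLinkProb,peakCoverageBg,peakCoverageEnriched,nCellTypes,seed
#'   see slots.
#' @return A validated `SimulationConfig`.
#' @examples
#' simulationConfig(seed = 7L)
#' @export
simulationConfig <- function(nGenes = 2000L, nLoci = 50L,
                             genesPerLocusMean = 2.8,
                             criterionRates = c(missense = 0.014,
                                                eqtl = 0.09,
                                                textmining = 0.17,
                                                ppi_seed = 0.014,
                                                somatic = 0.04,
                                                ko_phenotype = 0.18,
                                                functional = 0.15),
                             plantedGenes = 35L, elevatedRate = 0.7,
                             ppiEdgeProb = 0.002, nDrugTargets = 150L,
                             nCrcTargets = 8L, plantedLinkProb = 0.5,
                             peakCoverageBg = 0.05,
                             peakCoverageEnriched = 0.8,
                             nCellTypes = 34L, seed = 1L) {
  new("SimulationConfig", nGenes = as.integer(nGenes),
      nLoci = as.integer(nLoci),
      genesPerLocusMean = as.numeric(genesPerLocusMean),
      criterionRates = as.numeric(criterionRates),
      plantedGenes = as.integer(plantedGenes),
      elevatedRate = as.numeric(elevatedRate),
      ppiEdgeProb = as.numeric(ppiEdgeProb),
      nDrugTargets = as.integer(nDrugTargets),
      nCrcTargets = as.integer(nCrcTargets),
      plantedLinkProb = as.numeric(plantedLinkProb),
      peakCoverageBg = as.numeric(peakCoverageBg),
      peakCoverageEnriched = as.numeric(peakCoverageEnriched),
      nCellTypes = as.integer(nCellTypes), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d genes, %d loci (~%.1f genes each), %d planted @ rate %.2f, seed %d\n",
    object@nGenes, object@nLoci, object@genesPerLocusMean,
    object@plantedGenes, object@elevatedRate, object@seed))
})
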