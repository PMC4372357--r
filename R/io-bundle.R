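#' Construct a ResourceBundle
#'
#' Assembles the pipeline's inputs into a validated
#' [ResourceBundle-class]. All slots have empty defaults so partial
#' bundles can be built for single-stage use. `geneUniverseN` defaults to
#' the PPI node count — the hypergeometric universe N is a property of
#' the interaction snapshot, not derivable from the other tables, so
#' supply it explicitly when known.
#'
#' @param riskSnps,ld,consequences,eqtl,snpUniverse,network,drugs
#'   data.frames in the layouts of the corresponding readers.
#' @param genes `GRanges` with a `symbol` column ([readGeneBed()]).
#' @param textminingP,ppiSeedP named numeric gene -> p.
#' @param somaticGenes character symbol set.
#' @param koCategories,functionalTerms named lists of symbol sets.
#' @param peaks named list of `GRanges` (cell type -> peaks).
#' @param geneUniverseN integer universe size for overlap tests.
#' @return A `ResourceBundle`.
#' @export
resourceBundle <- function(riskSnps = emptyRiskSnps(), ld = emptyLd(),
                           genes = emptyGenes(),
                           consequences = data.frame(rsid = character(),
                                                     gene = character(),
                                                     consequence = character()),
                           eqtl = data.frame(rsid = character(),
                                             gene = character(),
                                             p = numeric(), fdr = numeric(),
                                             distance = numeric()),
                           textminingP = setNames(numeric(), character()),
                           ppiSeedP = setNames(numeric(), character()),
                           somaticGenes = character(),
                           koCategories = setNames(list(), character()),
                           functionalTerms = setNames(list(), character()),
                           peaks = setNames(list(), character()),
                           snpUniverse = data.frame(chrom = character(),
                                                    pos = integer()),
                           network = data.frame(from = character(),
                                                to = character()),
                           drugs = data.frame(drug = character(),
                                              target = character(),
                                              status = character(),
                                              indication = character(),
                                              crc_approved = logical()),
                           geneUniverseN = NULL) {
  network <- canonicalizeEdges(network)
  if (is.null(geneUniverseN))
    geneUniverseN <- length(unique(c(network$from, network$to)))
  new("ResourceBundle", riskSnps = riskSnps, ld = ld, genes = genes,
      consequences = consequences, eqtl = eqtl,
      textminingP = textminingP, ppiSeedP = ppiSeedP,
      somaticGenes = normSymbol(somaticGenes),
      koCategories = koCategories, functionalTerms = functionalTerms,
      peaks = peaks, snpUniverse = snpUniverse, network = network,
      drugs = drugs, geneUniverseN = as.integer(geneUniverseN))
}

emptyRiskSnps <- function()
  data.frame(rsid = character(), chrom = character(), pos = integer(),
             region = character(), assoc_p = numeric(),
             odds_ratio = numeric(), ci_low = numeric(),
             ci_high = numeric())

emptyLd <- function()
  data.frame(lead_rsid = character(), proxy_rsid = character(),
             r2 = numeric(), proxy_chrom = character(),
             proxy_pos = integer())

emptyGenes <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$symbol <- character()
  gr
}

.bundleFiles <- c(riskSnps = "risk_snps.tsv", ld = "ld.tsv",
                  genes = "genes.bed", consequences = "consequences.tsv",
                  eqtl = "eqtl.tsv", textminingP = "textmining_p.tsv",
                  ppiSeedP = "ppi_seed_p.tsv",
                  somaticGenes = "somatic_genes.gmt",
                  koCategories = "ko_categories.gmt",
                  functionalTerms = "functional_terms.gmt",
                  snpUniverse = "snp_universe.tsv",
                  network = "network.tsv", drugs = "drugs.tsv",
                  meta = "bundle.yaml")

#' Write / read a ResourceBundle as a plain-text directory
#'
#' The on-disk form is one TSV/BED/GMT file per resource plus a
#' `bundle.yaml` with the universe size, and a `peaks/` directory with
#' one BED per cell type (file name = cell type). Every reader
#' round-trips: `readBundle(writeBundle(b, d))` equals `b`.
#'
#' @param bundle A [ResourceBundle-class].
#' @param dir Directory to create/read.
#' @return `writeBundle()` the directory path, invisibly;
#'   `readBundle()` a `ResourceBundle`.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(nm) file.path(dir, .bundleFiles[[nm]])
  writeGwasTable(bundle@riskSnps, f("riskSnps"))
  writeLdTable(bundle@ld, f("ld"))
  writeBed(bundle@genes, f("genes"))
  writeConsequenceTable(bundle@consequences, f("consequences"))
  writeEqtlTable(bundle@eqtl, f("eqtl"))
  writeGenePvalues(bundle@textminingP, f("textminingP"))
  writeGenePvalues(bundle@ppiSeedP, f("ppiSeedP"))
  writeGeneSets(list(somatic = bundle@somaticGenes), f("somaticGenes"))
  writeGeneSets(bundle@koCategories, f("koCategories"))
  writeGeneSets(bundle@functionalTerms, f("functionalTerms"))
  writeSnpUniverse(bundle@snpUniverse, f("snpUniverse"))
  writeEdgeList(bundle@network, f("network"))
  writeDrugTable(bundle@drugs, f("drugs"))
  yaml::write_yaml(list(gene_universe_n = bundle@geneUniverseN,
                        cell_types = names(bundle@peaks)), f("meta"))
  pk <- file.path(dir, "peaks")
  dir.create(pk, showWarnings = FALSE)
  for (ct in names(bundle@peaks))
    writeBed(bundle@peaks[[ct]], file.path(pk, paste0(ct, ".bed")))
  invisible(dir)
}

#' @rdname writeBundle
#' @export
readBundle <- function(dir) {
  f <- function(nm) {
    p <- file.path(dir, .bundleFiles[[nm]])
    if (!file.exists(p)) stopf("bundle resource missing: %s", p)
    p
  }
  meta <- yaml::read_yaml(f("meta"))
  peaks <- setNames(list(), character())
  for (ct in meta$cell_types) {
    p <- file.path(dir, "peaks", paste0(ct, ".bed"))
    if (!file.exists(p)) stopf("bundle resource missing: %s", p)
    peaks[[ct]] <- readBed(p)
  }
  somatic <- readGeneSets(f("somaticGenes"))
  resourceBundle(
    riskSnps = readGwasTable(f("riskSnps")),
    ld = readLdTable(f("ld")),
    genes = readGeneBed(f("genes")),
    consequences = readConsequenceTable(f("consequences")),
    eqtl = readEqtlTable(f("eqtl")),
    textminingP = readGenePvalues(f("textminingP")),
    ppiSeedP = readGenePvalues(f("ppiSeedP")),
    somaticGenes = if (length(somatic)) somatic[[1L]] else character(),
    koCategories = readGeneSets(f("koCategories")),
    functionalTerms = readGeneSets(f("functionalTerms")),
    peaks = peaks,
    snpUniverse = readSnpUniverse(f("snpUniverse")),
    network = readEdgeList(f("network")),
    drugs = readDrugTable(f("drugs")),
    geneUniverseN = meta$gene_universe_n)
}

#' Read / write a pipeline configuration file
#'
#' YAML with keys mirroring the [PipelineConfig-class] constructor
#' arguments in snake_case (`r2_threshold`, `eqtl_fdr_max`, `eqtl_p_max`,
#' `eqtl_cis_window`, `gene_p_threshold`, `category_p_threshold`,
#' `score_threshold`, `permutation_iters`, `rng_seed`, `locus_flank_bp`,
#' `ease_adjust`, `match_locus_size`). Missing keys take the defaults.
#'
#' @param path YAML file.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  key <- function(nm, default) if (!is.null(y[[nm]])) y[[nm]] else default
  pipelineConfig(
    r2Threshold = key("r2_threshold", 0.80),
    eqtlFdrMax = key("eqtl_fdr_max", 0.50),
    eqtlPMax = key("eqtl_p_max", 0.0016),
    eqtlCisWindow = key("eqtl_cis_window", 250000),
    genePThreshold = key("gene_p_threshold", 0.05),
    categoryPThreshold = key("category_p_threshold", 0.05),
    scoreThreshold = key("score_threshold", 2L),
    permutationIters = key("permutation_iters", 100000L),
    rngSeed = key("rng_seed", 1L),
    locusFlankBp = key("locus_flank_bp", 0L),
    easeAdjust = key("ease_adjust", FALSE),
    matchLocusSize = key("match_locus_size", FALSE))
}

#' @rdname readPipelineConfig
#' @param cfg A `PipelineConfig`.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(list(
    r2_threshold = cfg@r2Threshold, eqtl_fdr_max = cfg@eqtlFdrMax,
    eqtl_p_max = cfg@eqtlPMax, eqtl_cis_window = cfg@eqtlCisWindow,
    gene_p_threshold = cfg@genePThreshold,
    category_p_threshold = cfg@categoryPThreshold,
    score_threshold = cfg@scoreThreshold,
    permutation_iters = cfg@permutationIters, rng_seed = cfg@rngSeed,
    locus_flank_bp = cfg@locusFlankBp, ease_adjust = cfg@easeAdjust,
    match_locus_size = cfg@matchLocusSize), path)
  invisible(path)
}
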