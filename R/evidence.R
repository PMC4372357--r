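## The seven binary prioritization criteria. Each criterion is a pure
## function of (bundle, config); indicators are 0/1 integers. All
## significance thresholds are strict "<".

.proxiesOf <- function(rsid, ld, r2Threshold) {
  unique(ld$proxy_rsid[ld$lead_rsid == rsid & ld$r2 > r2Threshold])
}

#' Criterion 1: missense consequence
#'
#' 1 iff the lead SNP, or any LD proxy at r2 strictly above the
#' threshold, carries a missense consequence annotated to this pair's
#' gene. A consequence in a different gene at the same locus does not
#' count. A SNP absent from the consequence table contributes 0.
#'
#' @param pair One-row data.frame with `rsid` and `gene`.
#' @param bundle A [ResourceBundle-class].
#' @param cfg A [PipelineConfig-class].
#' @return Integer 0 or 1.
#' @export
evalMissense <- function(pair, bundle, cfg = pipelineConfig()) {
  snps <- c(pair$rsid, .proxiesOf(pair$rsid, bundle@ld, cfg@r2Threshold))
  cs <- bundle@consequences
  as.integer(any(cs$rsid %in% snps & cs$gene == normSymbol(pair$gene) &
                 cs$consequence == "missense"))
}

#' Criterion 2: cis-eQTL support
#'
#' 1 iff an eQTL row links the pair's SNP to its gene with FDR, p and
#' SNP-probe distance all strictly below the configured bounds. When the
#' lead rsid is absent from the eQTL table entirely, the qualifying
#' proxy (r2 strictly above threshold) with the highest r2 that is
#' present substitutes for it; r2 ties break to the proxy whose best row
#' has the smaller distance.
#'
#' @inheritParams evalMissense
#' @return Integer 0 or 1.
#' @export
evalEqtl <- function(pair, bundle, cfg = pipelineConfig()) {
  eq <- bundle@eqtl
  rsid <- pair$rsid
  if (!rsid %in% eq$rsid) {
    ld <- bundle@ld
    px <- ld[ld$lead_rsid == rsid & ld$r2 > cfg@r2Threshold &
             ld$proxy_rsid %in% eq$rsid, , drop = FALSE]
    if (!nrow(px)) return(0L)
    bestDist <- vapply(px$proxy_rsid, function(r)
      min(eq$distance[eq$rsid == r]), numeric(1))
    rsid <- px$proxy_rsid[order(-px$r2, bestDist)][1L]
  }
  hit <- eq$rsid == rsid & eq$gene == normSymbol(pair$gene) &
    eq$fdr < cfg@eqtlFdrMax & eq$p < cfg@eqtlPMax &
    eq$distance < cfg@eqtlCisWindow
  as.integer(any(hit))
}

#' Criteria 3-4: per-gene p-value below threshold
#'
#' 1 iff the gene appears in the table with p strictly below the
#' threshold; absent genes score 0. Used for the text-mining and
#' PPI-seed score tables.
#'
#' @param gene Gene symbol.
#' @param table Named numeric vector, gene -> p.
#' @param threshold Significance cut-off (strict).
#' @return Integer 0 or 1.
#' @export
evalGenePvalue <- function(gene, table, threshold = 0.05) {
  g <- normSymbol(gene)
  as.integer(g %in% names(table) && table[[g]] < threshold)
}

#' Criterion 5: gene-set membership
#'
#' Case-insensitive membership of the gene in a symbol set (e.g. the
#' somatic-mutation catalogue).
#'
#' @param gene Gene symbol.
#' @param geneSet Character vector of symbols.
#' @return Integer 0 or 1.
#' @export
evalSetMembership <- function(gene, geneSet) {
  as.integer(normSymbol(gene) %in% normSymbol(geneSet))
}

#' Category enrichment of the candidate gene set
#'
#' For each category in a named gene-set collection, tests the overlap
#' between the candidate genes and the category with the exact
#' hypergeometric upper tail at universe size `universeN`
#' (EASE-adjusted when `cfg@easeAdjust`). Categories are returned sorted
#' by ascending p with a `significant` flag at the configured threshold
#' (strict).
#'
#' @param candidates Character set of candidate gene symbols.
#' @param collection Named list of symbol sets.
#' @param universeN Universe size; must cover candidates and every
#'   category.
#' @param cfg A [PipelineConfig-class].
#' @return data.frame: category, universe_n, category_k, draw_n,
#'   overlap_k, expected, fold, p_upper, significant.
#' @export
enrichCategories <- function(candidates, collection, universeN,
                             cfg = pipelineConfig()) {
  candidates <- unique(normSymbol(candidates))
  if (length(candidates) > universeN)
    stopf("universe (N = %d) smaller than candidate set (%d)",
          universeN, length(candidates))
  rows <- lapply(names(collection), function(nm) {
    cat <- unique(normSymbol(collection[[nm]]))
    if (length(cat) > universeN)
      stopf("category '%s' (%d genes) exceeds the universe (N = %d)",
            nm, length(cat), universeN)
    ot <- overlapTestCounts(universeN, length(cat), length(candidates),
                            length(intersect(candidates, cat)),
                            ease = cfg@easeAdjust)
    data.frame(category = nm, universe_n = ot@universeN,
               category_k = ot@categoryK, draw_n = ot@drawN,
               overlap_k = ot@overlapK, expected = ot@expected,
               fold = ot@fold, p_upper = ot@pUpper,
               significant = ot@pUpper < cfg@categoryPThreshold,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(category = character(), universe_n = integer(),
               category_k = integer(), draw_n = integer(),
               overlap_k = integer(), expected = numeric(),
               fold = numeric(), p_upper = numeric(),
               significant = logical())
  out <- out[order(out$p_upper, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Criteria 6-7: membership in an enriched category
#'
#' 1 iff the gene belongs to at least one category flagged significant
#' by [enrichCategories()]. The category-level enrichment is computed
#' once over the whole candidate set; this evaluates the gene-level
#' indicator derived from it (used for the knockout-phenotype and the
#' pooled functional-term collections).
#'
#' @param gene Gene symbol.
#' @param enrichments data.frame from [enrichCategories()].
#' @param collection The same named list the enrichment was computed on.
#' @return Integer 0 or 1.
#' @export
evalEnrichedMembership <- function(gene, enrichments, collection) {
  sig <- enrichments$category[enrichments$significant]
  g <- normSymbol(gene)
  for (nm in sig)
    if (g %in% normSymbol(collection[[nm]])) return(1L)
  0L
}

#' Evidence matrix: all seven criteria for every SNP-gene pair
#'
#' Evaluates the seven binary criteria per pair, deterministically given
#' bundle and config. Category enrichment (criteria 6-7) is computed
#' once over the distinct candidate genes, so rows are independent apart
#' from those shared enrichment flags; shuffling the pair order permutes
#' rows identically.
#'
#' @param pairs data.frame of SNP-gene pairs (rsid, gene, nearest), as
#'   from [mapAllLoci()].
#' @param bundle A [ResourceBundle-class].
#' @param cfg A [PipelineConfig-class].
#' @return data.frame in the report column order: snp, gene, nearest,
#'   missense, eqtl, textmining, ppi_seed, somatic, ko_phenotype,
#'   functional. The per-collection enrichment tables are attached as
#'   attributes `koEnrichment` and `functionalEnrichment`.
#' @export
buildEvidenceMatrix <- function(pairs, bundle, cfg = pipelineConfig()) {
  cols <- c("snp", "gene", "nearest", "missense", "eqtl", "textmining",
            "ppi_seed", "somatic", "ko_phenotype", "functional")
  if (!nrow(pairs)) {
    out <- data.frame(snp = character(), gene = character(),
                      nearest = logical(), missense = integer(),
                      eqtl = integer(), textmining = integer(),
                      ppi_seed = integer(), somatic = integer(),
                      ko_phenotype = integer(), functional = integer())
    return(out)
  }
  candidates <- unique(normSymbol(pairs$gene))
  koEnr <- enrichCategories(candidates, bundle@koCategories,
                            bundle@geneUniverseN, cfg)
  fnEnr <- enrichCategories(candidates, bundle@functionalTerms,
                            bundle@geneUniverseN, cfg)
  n <- nrow(pairs)
  out <- data.frame(
    snp = pairs$rsid, gene = normSymbol(pairs$gene),
    nearest = as.logical(pairs$nearest),
    missense = integer(n), eqtl = integer(n), textmining = integer(n),
    ppi_seed = integer(n), somatic = integer(n),
    ko_phenotype = integer(n), functional = integer(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pr <- data.frame(rsid = pairs$rsid[i], gene = out$gene[i])
    out$missense[i] <- evalMissense(pr, bundle, cfg)
    out$eqtl[i] <- evalEqtl(pr, bundle, cfg)
    out$textmining[i] <- evalGenePvalue(pr$gene, bundle@textminingP,
                                        cfg@genePThreshold)
    out$ppi_seed[i] <- evalGenePvalue(pr$gene, bundle@ppiSeedP,
                                      cfg@genePThreshold)
    out$somatic[i] <- evalSetMembership(pr$gene, bundle@somaticGenes)
    out$ko_phenotype[i] <- evalEnrichedMembership(pr$gene, koEnr,
                                                  bundle@koCategories)
    out$functional[i] <- evalEnrichedMembership(pr$gene, fnEnr,
                                                bundle@functionalTerms)
  }
  attr(out, "koEnrichment") <- koEnr
  attr(out, "functionalEnrichment") <- fnEnr
  out[, cols]
}

.criterionCols <- c("missense", "eqtl", "textmining", "ppi_seed",
                    "somatic", "ko_phenotype", "functional")

#' Pairwise Pearson correlation of the seven criteria
#'
#' The scoring model treats the criteria as roughly independent pieces
#' of evidence; this check quantifies their pairwise Pearson
#' correlations across pairs. Zero-variance columns yield `NA`
#' (undefined) entries — never 0 — including their diagonal. The maximum
#' off-diagonal r-squared is attached as attribute `maxOffDiagR2`.
#'
#' @param matrix Evidence matrix from [buildEvidenceMatrix()] (at least
#'   2 rows).
#' @return 7x7 symmetric correlation matrix.
#' @export
criterionCorrelation <- function(matrix) {
  if (nrow(matrix) < 2L)
    stopf("criterion correlation needs at least 2 evidence rows")
  m <- as.matrix(matrix[, .criterionCols])
  storage.mode(m) <- "double"
  sds <- apply(m, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  off <- cc[upper.tri(cc)]
  attr(cc, "maxOffDiagR2") <- if (all(is.na(off))) NA_real_ else
    max(off[!is.na(off)]^2)
  cc
}
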