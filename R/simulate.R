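## Synthetic resource bundles with planted, recoverable structure.
##
## The generator works top-down: it first draws the binary indicator
## matrix it wants the evidence stage to recover (elevated success rates
## for planted genes, background rates otherwise) and then constructs
## each resource table so that criterion evaluation reproduces that
## matrix exactly. This inverse construction is the primary correctness
## harness for the evidence module. Chromosomes are abstract
## ("chrS1"...), no genome build is referenced.

.GENE_LEN <- 2000L
.GENE_GAP <- 3000L
.N_CHROM <- 5L

## decode linear upper-triangle pair index k (1..n(n-1)/2) into (i, j)
.pairDecode <- function(k, n) {
  total <- n * (n - 1) / 2
  k0 <- total - k
  r <- floor((sqrt(8 * k0 + 1) - 1) / 2)
  i <- n - 1 - r
  j <- n - (k0 - r * (r + 1) / 2)
  cbind(as.integer(i), as.integer(j))
}

#' Simulate a complete resource bundle with planted ground truth
#'
#' Generates every table a [ResourceBundle-class] holds, plus the ground
#' truth needed to check recovery: gene models on abstract chromosomes
#' with non-overlapping bodies; risk loci as runs of consecutive genes
#' spanned by high-r2 LD proxies (so locus mapping recovers exactly the
#' run); a drawn 7-criterion indicator matrix (planted genes succeed at
#' `elevatedRate`, others at the background `criterionRates`) with every
#' criterion resource built so evidence evaluation reproduces the drawn
#' matrix; an Erdos-Renyi PPI graph plus planted links between planted
#' genes and disease-approved drug targets; a drug-target table; a SNP
#' universe; and per-cell-type peak sets with the first cell type
#' enriched over the loci. Deterministic given `cfg@seed`.
#'
#' @param cfg A [SimulationConfig-class].
#' @return List with elements `bundle` (a `ResourceBundle`) and `truth`
#'   (list: plantedGenes, indicators — the drawn matrix keyed by
#'   snp/gene —, expectedColumnSums, realizedColumnSums, drugFold,
#'   enrichedCellTypes, pipelineConfig).
#' @seealso [nullBundle()]
#' @export
simulateBundle <- function(cfg = simulationConfig()) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(cfg@seed)
  nG <- cfg@nGenes

  ## --- gene models -------------------------------------------------
  perChrom <- ceiling(nG / .N_CHROM)
  chromOf <- rep(sprintf("chrS%d", seq_len(.N_CHROM)), each = perChrom)[1:nG]
  slot <- sequence(rle(chromOf)$lengths) - 1L
  starts <- .GENE_GAP + slot * (.GENE_LEN + .GENE_GAP) + 1L
  sym <- sprintf("GENE%05d", seq_len(nG))
  genes <- GenomicRanges::GRanges(
    chromOf, IRanges::IRanges(starts, starts + .GENE_LEN - 1L))
  S4Vectors::mcols(genes)$symbol <- sym

  ## --- loci: disjoint runs of consecutive genes --------------------
  sizes <- pmax(1L, rpois(cfg@nLoci, max(cfg@genesPerLocusMean - 1, 0)) + 1L)
  gaps <- sample(2:6, cfg@nLoci, replace = TRUE)
  runStart <- integer(cfg@nLoci); ptr <- 1L
  for (j in seq_len(cfg@nLoci)) {
    ptr <- ptr + gaps[j]
    ## keep the run within one chromosome
    while (ptr + sizes[j] - 1L <= nG &&
           chromOf[ptr] != chromOf[ptr + sizes[j] - 1L]) ptr <- ptr + 1L
    if (ptr + sizes[j] - 1L > nG)
      stopf("infeasible placement: %d loci of mean size %.1f exceed %d genes",
            cfg@nLoci, cfg@genesPerLocusMean, nG)
    runStart[j] <- ptr
    ptr <- ptr + sizes[j]
  }
  leadRsid <- sprintf("rsS%04d", seq_len(cfg@nLoci))
  leadPos <- starts[runStart] + .GENE_LEN %/% 2L
  riskSnps <- data.frame(
    rsid = leadRsid, chrom = chromOf[runStart], pos = leadPos,
    region = sprintf("locus%02d", seq_len(cfg@nLoci)),
    assoc_p = signif(10^runif(cfg@nLoci, -28, -6), 3),
    odds_ratio = round(runif(cfg@nLoci, 1.05, 1.5), 2),
    ci_low = NA_real_, ci_high = NA_real_, stringsAsFactors = FALSE)

  ## two high-r2 proxies bracketing the run, one sub-threshold decoy
  ld <- do.call(rbind, lapply(seq_len(cfg@nLoci), function(j) {
    lastG <- runStart[j] + sizes[j] - 1L
    data.frame(
      lead_rsid = leadRsid[j],
      proxy_rsid = sprintf("%sP%d", leadRsid[j], 1:3),
      r2 = c(0.95, 0.9, 0.5),
      proxy_chrom = chromOf[runStart[j]],
      proxy_pos = c(starts[runStart[j]] + 1L,
                    starts[lastG] + .GENE_LEN - 2L,
                    max(1L, starts[runStart[j]] - 40000L)),
      stringsAsFactors = FALSE)
  }))

  ## candidate pairs: locus lead x genes of the run, nearest = first
  pairs <- do.call(rbind, lapply(seq_len(cfg@nLoci), function(j) {
    gi <- runStart[j]:(runStart[j] + sizes[j] - 1L)
    data.frame(rsid = leadRsid[j], gene = sym[gi],
               nearest = gi == runStart[j], stringsAsFactors = FALSE)
  }))
  candGenes <- unique(pairs$gene)

  ## --- draw the target indicator matrix ----------------------------
  nPlant <- min(cfg@plantedGenes, length(candGenes))
  planted <- if (nPlant) sample(candGenes, nPlant) else character()
  rateFor <- function(g, j)
    ifelse(g %in% planted, cfg@elevatedRate, cfg@criterionRates[j])
  geneLevel <- c(textmining = 3L, ppi_seed = 4L, somatic = 5L,
                 ko_phenotype = 6L, functional = 7L)
  gFlag <- matrix(0L, length(candGenes), length(geneLevel),
                  dimnames = list(candGenes, names(geneLevel)))
  for (nm in names(geneLevel))
    gFlag[, nm] <- rbinom(length(candGenes), 1L,
                          rateFor(candGenes, geneLevel[[nm]]))
  ind <- data.frame(
    snp = pairs$rsid, gene = pairs$gene, nearest = pairs$nearest,
    missense = rbinom(nrow(pairs), 1L, rateFor(pairs$gene, 1L)),
    eqtl = rbinom(nrow(pairs), 1L, rateFor(pairs$gene, 2L)),
    stringsAsFactors = FALSE)
  for (nm in names(geneLevel)) ind[[nm]] <- gFlag[pairs$gene, nm]

  ## --- inverse-construct the criterion resources -------------------
  nonCand <- setdiff(sym, candGenes)
  consequences <- rbind(
    if (any(ind$missense == 1L))
      data.frame(rsid = ind$snp[ind$missense == 1L],
                 gene = ind$gene[ind$missense == 1L],
                 consequence = "missense", stringsAsFactors = FALSE),
    data.frame(rsid = ind$snp[ind$missense == 0L],
               gene = ind$gene[ind$missense == 0L],
               consequence = "intronic", stringsAsFactors = FALSE))
  eqtl <- if (any(ind$eqtl == 1L))
    data.frame(rsid = ind$snp[ind$eqtl == 1L],
               gene = ind$gene[ind$eqtl == 1L],
               p = 1e-4, fdr = 0.1, distance = 1000,
               stringsAsFactors = FALSE)
  else data.frame(rsid = character(), gene = character(), p = numeric(),
                  fdr = numeric(), distance = numeric())
  pvTable <- function(col) {
    on <- candGenes[gFlag[, col] == 1L]
    off <- candGenes[gFlag[, col] == 0L]
    setNames(c(rep(0.01, length(on)), rep(0.5, length(off))),
             c(on, off))
  }
  textminingP <- pvTable("textmining")
  ppiSeedP <- pvTable("ppi_seed")
  somaticGenes <- c(candGenes[gFlag[, "somatic"] == 1L],
                    sample(nonCand, min(100L, length(nonCand))))

  ## enriched-category collections: one category holding exactly the
  ## flagged candidates (plus filler chosen to keep it significant),
  ## background categories of non-candidate genes only
  mkCollection <- function(col, prefix, nBackground) {
    flagged <- candGenes[gFlag[, col] == 1L]
    coll <- list()
    if (length(flagged) >= 1L) {
      filler <- sample(nonCand, min(20L, length(nonCand)))
      repeat {
        K <- length(flagged) + length(filler)
        p <- hypergeomUpperTail(nG, K, length(candGenes), length(flagged))
        if (p < 0.05 || !length(filler)) break
        filler <- filler[-length(filler)]
      }
      if (p < 0.05)
        coll[[paste0(prefix, "_planted")]] <- c(flagged, filler)
      else {
        ## too few flagged genes to reach significance: retract the flags
        gFlag[, col] <<- 0L
        ind[[col]] <<- 0L
      }
    }
    for (b in seq_len(nBackground)) {
      coll[[sprintf("%s_bg%02d", prefix, b)]] <-
        sample(nonCand, min(30L, length(nonCand)))
    }
    coll
  }
  koCategories <- mkCollection("ko_phenotype", "ko", 29L)
  functionalTerms <- c(mkCollection("functional", "go", 10L),
                       lapply(setNames(1:3, sprintf("kegg_bg%02d", 1:3)),
                              function(i) sample(nonCand, min(25L, length(nonCand)))),
                       lapply(setNames(1:3, sprintf("omim_bg%02d", 1:3)),
                              function(i) sample(nonCand, min(15L, length(nonCand)))))

  ## --- PPI network: background ER + planted drug links --------------
  totalPairs <- nG * (nG - 1) / 2
  m <- rbinom(1L, size = min(totalPairs, .Machine$integer.max),
              prob = cfg@ppiEdgeProb)
  kIdx <- sample(totalPairs, min(m, totalPairs))
  ij <- .pairDecode(kIdx, nG)
  network <- data.frame(from = sym[ij[, 1L]], to = sym[ij[, 2L]],
                        stringsAsFactors = FALSE)

  drugTargets <- sample(nonCand, cfg@nDrugTargets)
  crcTargets <- drugTargets[seq_len(cfg@nCrcTargets)]
  if (length(planted) && cfg@plantedLinkProb > 0) {
    link <- expand.grid(from = planted, to = crcTargets,
                        stringsAsFactors = FALSE)
    link <- link[runif(nrow(link)) < cfg@plantedLinkProb, , drop = FALSE]
    network <- rbind(network, link)
  }
  statuses <- sample(c("approved", "clinical", "experimental"),
                     cfg@nDrugTargets, replace = TRUE)
  statuses[seq_len(cfg@nCrcTargets)] <- "approved"
  drugs <- data.frame(
    drug = sprintf("drug_%03d", seq_len(cfg@nDrugTargets)),
    target = drugTargets, status = statuses,
    indication = ifelse(seq_len(cfg@nDrugTargets) <= cfg@nCrcTargets,
                        "colorectal cancer", "other"),
    crc_approved = seq_len(cfg@nDrugTargets) <= cfg@nCrcTargets,
    stringsAsFactors = FALSE)

  ## --- SNP universe and peak sets ----------------------------------
  chromLen <- .GENE_GAP + perChrom * (.GENE_LEN + .GENE_GAP)
  lociMembers <- data.frame(
    chrom = c(riskSnps$chrom, ld$proxy_chrom),
    pos = c(riskSnps$pos, ld$proxy_pos), stringsAsFactors = FALSE)
  extra <- data.frame(
    chrom = sample(sprintf("chrS%d", seq_len(.N_CHROM)), 3000L,
                   replace = TRUE),
    pos = sample.int(chromLen, 3000L, replace = TRUE),
    stringsAsFactors = FALSE)
  snpUniverse <- unique(rbind(lociMembers, extra))

  peaks <- setNames(vector("list", cfg@nCellTypes),
                    if (cfg@nCellTypes)
                      sprintf("celltype_%02d", seq_len(cfg@nCellTypes))
                    else character())
  enriched <- logical(cfg@nCellTypes)
  bgPeaksFor <- function() {
    take <- which(runif(nrow(snpUniverse)) < cfg@peakCoverageBg)
    if (!length(take)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(.posGRanges(snpUniverse$chrom[take],
                                      snpUniverse$pos[take]) + 50L)
  }
  if (cfg@nCellTypes >= 1L) {
    cover <- which(runif(cfg@nLoci) < cfg@peakCoverageEnriched)
    enrichedPeaks <- if (length(cover))
      GenomicRanges::reduce(c(
        .posGRanges(riskSnps$chrom[cover], riskSnps$pos[cover]) + 250L,
        bgPeaksFor()))
    else bgPeaksFor()
    peaks[[1L]] <- enrichedPeaks
    enriched[1L] <- cfg@peakCoverageEnriched > cfg@peakCoverageBg
    for (ct in seq_len(cfg@nCellTypes)[-1L]) peaks[[ct]] <- bgPeaksFor()
  }

  bundle <- resourceBundle(
    riskSnps = riskSnps, ld = ld, genes = genes,
    consequences = consequences, eqtl = eqtl,
    textminingP = textminingP, ppiSeedP = ppiSeedP,
    somaticGenes = somaticGenes, koCategories = koCategories,
    functionalTerms = functionalTerms, peaks = peaks,
    snpUniverse = snpUniverse, network = network, drugs = drugs,
    geneUniverseN = nG)

  ## --- ground truth -------------------------------------------------
  critCols <- c("missense", "eqtl", "textmining", "ppi_seed", "somatic",
                "ko_phenotype", "functional")
  nPairs <- nrow(ind)
  isPlanted <- ind$gene %in% planted
  expSums <- vapply(seq_along(critCols), function(j)
    sum(ifelse(isPlanted, cfg@elevatedRate, cfg@criterionRates[j])),
    numeric(1))
  names(expSums) <- critCols
  score <- rowSums(ind[, critCols])
  bioGenes <- unique(ind$gene[score >= 2])
  xTrue <- if (length(bioGenes)) oneHopExpand(bioGenes, bundle@network)
           else character()
  ky <- length(intersect(xTrue, normSymbol(crcTargets)))
  drugFold <- if (length(xTrue))
    ky / (cfg@nCrcTargets * length(xTrue) / nG) else NA_real_
  truth <- list(
    plantedGenes = sort(planted),
    indicators = ind,
    expectedColumnSums = expSums,
    realizedColumnSums = colSums(ind[, critCols]),
    biologicalGenes = sort(bioGenes),
    drugFold = drugFold,
    crcOverlap = ky,
    enrichedCellTypes = setNames(enriched, names(peaks)),
    seed = cfg@seed)
  list(bundle = bundle, truth = truth)
}

#' Null resource bundle: all planted effects switched off
#'
#' Same generator as [simulateBundle()] with no planted genes, no
#' planted drug links, and the enriched cell type's coverage lowered to
#' background, for type-I-error and p-uniformity checks. The ground
#' truth's planted set is empty.
#'
#' @param cfg A [SimulationConfig-class]; the planted fields are
#'   overridden.
#' @return As [simulateBundle()].
#' @export
nullBundle <- function(cfg = simulationConfig()) {
  cfg@plantedGenes <- 0L
  cfg@plantedLinkProb <- 0
  cfg@peakCoverageEnriched <- cfg@peakCoverageBg
  simulateBundle(cfg)
}
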