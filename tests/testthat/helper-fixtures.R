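## Shared in-code fixtures for the unit tests.

## A small hand-built bundle: one chromosome, four genes, two risk loci.
## Locus rs1 (pos 1500, inside GA) has proxies spanning GA..GB; locus
## rs2 (pos 9500, inside GD) has no qualifying proxies.
tinyBundle <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1001, 3001, 6001, 9001),
                             end = c(2000, 4000, 7000, 10000)))
  S4Vectors::mcols(genes)$symbol <- c("GA", "GB", "GC", "GD")
  riskSnps <- data.frame(
    rsid = c("rs1", "rs2"), chrom = "chr1", pos = c(1500L, 9500L),
    region = c("r1", "r2"), assoc_p = c(1e-8, 1e-7),
    odds_ratio = c(1.2, 1.1), ci_low = NA_real_, ci_high = NA_real_,
    stringsAsFactors = FALSE)
  ld <- data.frame(
    lead_rsid = c("rs1", "rs1", "rs1"),
    proxy_rsid = c("rs1p1", "rs1p2", "rs1weak"),
    r2 = c(0.95, 0.85, 0.5),
    proxy_chrom = "chr1",
    proxy_pos = c(1100L, 3500L, 500L), stringsAsFactors = FALSE)
  consequences <- data.frame(
    rsid = c("rs1p1", "rs1"), gene = c("GA", "GB"),
    consequence = c("missense", "intronic"), stringsAsFactors = FALSE)
  eqtl <- data.frame(
    rsid = c("rs1", "rs1", "rs2p"), gene = c("GB", "GA", "GD"),
    p = c(1e-4, 0.5, 1e-5), fdr = c(0.1, 0.9, 0.2),
    distance = c(1000, 1000, 2000), stringsAsFactors = FALSE)
  resourceBundle(
    riskSnps = riskSnps, ld = ld, genes = genes,
    consequences = consequences, eqtl = eqtl,
    textminingP = c(GA = 0.01, GB = 0.2, GD = 0.049),
    ppiSeedP = c(GB = 0.04),
    somaticGenes = c("GA", "GD"),
    koCategories = list(ko1 = c("GA", "GB"), ko2 = c("GC")),
    functionalTerms = list(f1 = c("GA"), f2 = c("GD", "ZZ1")),
    peaks = list(ct1 = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(1400, 1600))),
    snpUniverse = data.frame(chrom = "chr1",
                             pos = as.integer(seq(100, 12000, by = 100))),
    network = data.frame(from = c("GA", "GB"), to = c("T1", "T2"),
                         stringsAsFactors = FALSE),
    drugs = data.frame(
      drug = c("d1", "d2"), target = c("T1", "T2"),
      status = c("approved", "approved"),
      indication = c("colorectal cancer", "other"),
      crc_approved = c(TRUE, FALSE), stringsAsFactors = FALSE),
    geneUniverseN = 100L)
}

## Build the score records / network / drug table realizing the packaged
## overlap scenario, so drugOverlapReport() can be exercised end to end.
overlapScenarioInputs <- function() {
  sc <- fixtureOverlapScenario()
  seeds <- sc$x[554:584]                     # 31 of the x labels as seeds
  others <- setdiff(sc$x, seeds)             # remaining 553 = one-hop hits
  hub <- seeds[1L]
  network <- data.frame(from = hub, to = others, stringsAsFactors = FALSE)
  drugs <- data.frame(
    drug = sprintf("drug%04d", seq_along(sc$z)),
    target = sc$z,
    status = "approved",
    indication = ifelse(sc$z %in% sc$y, "colorectal cancer", "other"),
    crc_approved = sc$z %in% sc$y, stringsAsFactors = FALSE)
  records <- data.frame(
    snp = sprintf("rs%03d", seq_along(seeds)), gene = seeds,
    nearest = TRUE, score = 2L, biological = TRUE,
    stringsAsFactors = FALSE)
  list(scenario = sc, records = records, network = network, drugs = drugs)
}

## Brute-force hypergeometric pmf / upper tail from plain choose()
## ratios (independent of the log-space implementation).
enumTail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

criterionCols <- c("missense", "eqtl", "textmining", "ppi_seed",
                   "somatic", "ko_phenotype", "functional")
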