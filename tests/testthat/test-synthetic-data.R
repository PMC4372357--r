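test_that("the generator is deterministic given its seed", {
  cfg <- simulationConfig(nGenes = 600L, nLoci = 20L, nCellTypes = 3L,
                          seed = 7L)
  s1 <- simulateBundle(cfg)
  s2 <- simulateBundle(cfg)
  expect_equal(s1$truth$indicators, s2$truth$indicators)
  expect_equal(s1$bundle@riskSnps, s2$bundle@riskSnps)
  expect_equal(s1$bundle@network, s2$bundle@network, ignore_attr = TRUE)
  ## byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeBundle(s1$bundle, d1); writeBundle(s2$bundle, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("evidence evaluation recovers the planted indicator matrix", {
  ## the generator's inverse construction is the evidence module's
  ## primary correctness harness: recovery must be exact
  for (seed in c(7L, 19L)) {
    sim <- simulateBundle(simulationConfig(seed = seed, nCellTypes = 2L))
    pairs <- mapAllLoci(sim$bundle)
    key <- function(df, s, g) paste(df[[s]], df[[g]])
    expect_setequal(key(pairs, "rsid", "gene"),
                    key(sim$truth$indicators, "snp", "gene"))
    ev <- buildEvidenceMatrix(pairs, sim$bundle)
    m <- merge(ev, sim$truth$indicators, by.x = c("snp", "gene"),
               by.y = c("snp", "gene"), suffixes = c("", ".truth"))
    expect_equal(nrow(m), nrow(ev))
    for (cc in criterionCols)
      expect_equal(m[[cc]], m[[paste0(cc, ".truth")]], label = cc)
    ## nearest flags agree too
    expect_equal(sum(ev$nearest), length(unique(ev$snp)))
  }
})

test_that("planted genes separate from background in score", {
  cfg <- simulationConfig(seed = 5L, nGenes = 3000L, nLoci = 80L,
                          genesPerLocusMean = 4,
                          criterionRates = rep(0.05, 7),
                          plantedGenes = 40L, elevatedRate = 0.8,
                          nCellTypes = 0L)
  sim <- simulateBundle(cfg)
  ind <- sim$truth$indicators
  score <- rowSums(ind[, criterionCols])
  planted <- ind$gene %in% sim$truth$plantedGenes
  expect_gt(mean(score[planted]), 4)
  expect_lt(mean(score[!planted]), 1)
})

test_that("with no elevation planted genes look like background", {
  cfg <- simulationConfig(seed = 23L, nGenes = 5000L, nLoci = 250L,
                          genesPerLocusMean = 4,
                          criterionRates = rep(0.1, 7),
                          plantedGenes = 450L, elevatedRate = 0.1,
                          nCellTypes = 0L)
  sim <- simulateBundle(cfg)
  ind <- sim$truth$indicators
  score <- rowSums(ind[, criterionCols])
  planted <- ind$gene %in% sim$truth$plantedGenes
  expect_gt(sum(planted), 100)
  expect_lt(abs(mean(score[planted]) - mean(score[!planted])), 0.1)
})

test_that("realized criterion sums track their expectations", {
  sim <- simulateBundle(simulationConfig(seed = 31L, nCellTypes = 0L))
  exp <- sim$truth$expectedColumnSums
  real <- sim$truth$realizedColumnSums
  ind <- sim$truth$indicators
  planted <- ind$gene %in% sim$truth$plantedGenes
  for (j in seq_along(criterionCols)) {
    rates <- ifelse(planted, 0.7,
                    simulationConfig()@criterionRates[j])
    sd3 <- 3 * sqrt(sum(rates * (1 - rates)))
    ## ko/functional may be retracted to 0 when too sparse to enrich;
    ## retraction only ever lowers the realized sum
    expect_lte(real[[j]], exp[[j]] + sd3)
    if (real[[j]] > 0) expect_gte(real[[j]], exp[[j]] - sd3)
  }
})

test_that("null bundles carry no planted structure", {
  nb <- nullBundle(simulationConfig(seed = 3L, nCellTypes = 3L))
  expect_length(nb$truth$plantedGenes, 0L)
  expect_false(any(nb$truth$enrichedCellTypes))
  ## no planted drug links: CRC targets are not systematically wired
  ## to biological genes beyond the background graph
  expect_true(all(!nb$bundle@drugs$target %in%
                  nb$truth$indicators$gene))
})

test_that("the drug-overlap test controls its type-I error under the null", {
  ## with no planted links the disease-target overlap should reject at
  ## most at the nominal rate; the discrete exact test is conservative,
  ## so the observed fraction may fall well below it
  ps <- vapply(1:25, function(seed) {
    nb <- nullBundle(simulationConfig(seed = seed, nGenes = 600L,
                                      nLoci = 20L, plantedGenes = 12L,
                                      nDrugTargets = 60L,
                                      nCrcTargets = 6L, nCellTypes = 0L))
    scored <- scoreRows(buildEvidenceMatrix(mapAllLoci(nb$bundle),
                                            nb$bundle))
    rep <- drugOverlapReport(scored, ppiNetwork(nb$bundle),
                             drugTable(nb$bundle),
                             geneUniverseN(nb$bundle))
    pUpper(crcTest(rep))
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.1)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("generated bundles survive the full reader round-trip", {
  sim <- simulateBundle(simulationConfig(seed = 13L, nGenes = 500L,
                                         nLoci = 15L, nCellTypes = 2L))
  d <- withr::local_tempdir()
  writeBundle(sim$bundle, d)
  b2 <- readBundle(d)
  expect_equal(b2@riskSnps, sim$bundle@riskSnps)
  expect_equal(b2@eqtl, sim$bundle@eqtl)
  expect_equal(b2@koCategories, sim$bundle@koCategories)
  expect_equal(b2@network, sim$bundle@network, ignore_attr = TRUE)
  expect_equal(b2@geneUniverseN, sim$bundle@geneUniverseN)
})

test_that("infeasible locus placement errors out", {
  expect_error(
    simulateBundle(simulationConfig(nGenes = 30L, nLoci = 20L,
                                    genesPerLocusMean = 5,
                                    plantedGenes = 5L,
                                    nDrugTargets = 10L, nCrcTargets = 2L,
                                    seed = 1L)),
    "infeasible placement")
})

test_that("overlap-scenario fixture is invariant to label permutation", {
  sc <- fixtureOverlapScenario()
  expect_length(sc$x, 584L)
  expect_length(sc$y, 8L)
  expect_length(sc$z, 871L)
  expect_length(intersect(sc$x, sc$y), 5L)
  expect_length(intersect(sc$x, sc$z), 70L)
  expect_true(all(sc$y %in% sc$z))
  set.seed(99)
  relabel <- setNames(sprintf("L%05d", sample.int(20000, 11303))[
    seq_along(unique(c(sc$x, sc$z)))], unique(c(sc$x, sc$z)))
  rl <- function(v) unname(relabel[v])
  o1 <- overlapTest(sc$universeN, sc$y, sc$x)
  o2 <- overlapTest(sc$universeN, rl(sc$y), rl(sc$x))
  expect_equal(foldEnrichment(o2), foldEnrichment(o1))
  expect_equal(pUpper(o2), pUpper(o1))
})

test_that("published-table fixtures carry the printed structure", {
  t1 <- fixtureTable1()
  expect_equal(nrow(t1), 64L)
  expect_equal(sum(t1$rsid == "rs4939827"), 5L)
  expect_equal(max(t1$odds_ratio[t1$rsid == "rs6983267"]), 1.2)
  strongest <- t1[t1$rsid == "rs6983267", ]
  expect_equal(strongest$odds_ratio[which.min(strongest$assoc_p)], 1.2)
  t2 <- fixtureTable2()
  expect_equal(nrow(t2), 35L)
  expect_equal(length(unique(t2$gene)), 31L)
  expect_equal(t2$score[t2$snp == "rs3217810" & t2$gene == "CCND2"], 5L)
  expect_equal(sum(t2$ambiguous), 1L)
  expect_equal(t2$gene[t2$ambiguous == 1L], "SYNJ2")
})
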