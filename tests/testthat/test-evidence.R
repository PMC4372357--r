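pairOf <- function(rsid, gene)
  data.frame(rsid = rsid, gene = gene, stringsAsFactors = FALSE)

test_that("missense criterion is gene-specific and sees LD proxies", {
  b <- tinyBundle()
  ## missense sits on proxy rs1p1 (r2 = 0.95) annotated to GA
  expect_equal(evalMissense(pairOf("rs1", "GA"), b), 1L)
  ## same locus, different gene: the GB annotation is intronic
  expect_equal(evalMissense(pairOf("rs1", "GB"), b), 0L)
  ## SNP absent from the consequence table
  expect_equal(evalMissense(pairOf("rs2", "GD"), b), 0L)
  ## a sub-threshold proxy's missense must not count
  b2 <- b
  b2@consequences <- data.frame(rsid = "rs1weak", gene = "GB",
                                consequence = "missense")
  expect_equal(evalMissense(pairOf("rs1", "GB"), b2), 0L)
})

test_that("eQTL criterion applies strict bounds and proxy substitution", {
  b <- tinyBundle()
  expect_equal(evalEqtl(pairOf("rs1", "GB"), b), 1L)
  ## GA's row fails fdr < 0.5
  expect_equal(evalEqtl(pairOf("rs1", "GA"), b), 0L)
  ## rs2 is absent from the table; its only proxy row is rs2p but rs2
  ## has no LD proxies, so no substitution happens
  expect_equal(evalEqtl(pairOf("rs2", "GD"), b), 0L)
  ## give rs2 a qualifying proxy present in the table -> substitution
  b2 <- b
  b2@ld <- rbind(b2@ld, data.frame(lead_rsid = "rs2", proxy_rsid = "rs2p",
                                   r2 = 0.9, proxy_chrom = "chr1",
                                   proxy_pos = 9600L))
  expect_equal(evalEqtl(pairOf("rs2", "GD"), b2), 1L)
  ## boundary contracts are strict
  b3 <- b
  b3@eqtl <- data.frame(rsid = "rs1", gene = "GC",
                        p = c(1e-4, 1e-4, 0.0016),
                        fdr = c(0.6, 0.1, 0.1),
                        distance = c(1000, 250000, 1000))
  expect_equal(evalEqtl(pairOf("rs1", "GC"), b3), 0L)
})

test_that("gene p-value criterion uses a strict threshold", {
  tab <- c(GX = 0.049, GY = 0.05)
  expect_equal(evalGenePvalue("GX", tab), 1L)
  expect_equal(evalGenePvalue("GY", tab), 0L)
  expect_equal(evalGenePvalue("ABSENT", tab), 0L)
  expect_equal(evalGenePvalue("gx", tab), 1L)  # case-normalized
})

test_that("set membership is case-insensitive", {
  expect_equal(evalSetMembership("ROS1", c("ROS1", "GOPC")), 1L)
  expect_equal(evalSetMembership("Ros1", c("ROS1")), 1L)
  expect_equal(evalSetMembership("ROS1", character()), 0L)
})

test_that("category enrichment matches brute-force enumeration", {
  cands <- sprintf("G%02d", 1:12)
  coll <- list(hit = c(sprintf("G%02d", 1:6), "X1", "X2"),
               miss = sprintf("X%02d", 1:10))
  enr <- enrichCategories(cands, coll, universeN = 40L)
  expect_equal(enr$category, c("hit", "miss"))  # sorted by p
  for (i in seq_len(nrow(enr)))
    expect_equal(enr$p_upper[i],
                 enumTail(40, enr$category_k[i], enr$draw_n[i],
                          enr$overlap_k[i]),
                 tolerance = 1e-12)
  expect_true(enr$significant[enr$category == "hit"])
  expect_false(enr$significant[enr$category == "miss"])
  ## zero overlap everywhere -> nothing significant, p = 1
  none <- enrichCategories(cands, list(m = c("X1", "X2")), 40L)
  expect_equal(none$p_upper, 1)
  expect_false(any(none$significant))
  expect_error(enrichCategories(cands, list(big = sprintf("B%03d", 1:50)),
                                40L), "exceeds the universe")
})

test_that("enriched-membership indicator needs one significant category", {
  enr <- data.frame(category = c("sig", "notsig"),
                    significant = c(TRUE, FALSE))
  coll <- list(sig = c("GA", "GB"), notsig = c("GB", "GC"))
  expect_equal(evalEnrichedMembership("GB", enr, coll), 1L)
  expect_equal(evalEnrichedMembership("GC", enr, coll), 0L)
  expect_equal(evalEnrichedMembership("NONE", enr, coll), 0L)
})

test_that("evidence matrix is pure, order-equivariant and empty-safe", {
  b <- tinyBundle()
  pairs <- mapAllLoci(b)
  ev1 <- buildEvidenceMatrix(pairs, b)
  ev2 <- buildEvidenceMatrix(pairs, b)
  expect_identical(ev1, ev2)

  perm <- sample(seq_len(nrow(pairs)))
  evP <- buildEvidenceMatrix(pairs[perm, , drop = FALSE], b)
  rownames(evP) <- NULL
  expected <- ev1[perm, , drop = FALSE]
  rownames(expected) <- NULL
  expect_equal(evP, expected, ignore_attr = TRUE)

  empty <- buildEvidenceMatrix(pairs[0, , drop = FALSE], b)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty),
               c("snp", "gene", "nearest", criterionCols))
})

test_that("criteria are monotone when resources grow", {
  b <- tinyBundle()
  pairs <- mapAllLoci(b)
  ev <- buildEvidenceMatrix(pairs, b)
  ## enrich every resource and re-evaluate: no indicator may flip 1 -> 0
  b2 <- b
  b2@consequences <- rbind(b2@consequences,
                           data.frame(rsid = "rs2", gene = "GD",
                                      consequence = "missense"))
  b2@eqtl <- rbind(b2@eqtl,
                   data.frame(rsid = "rs1", gene = "GA", p = 1e-5,
                              fdr = 0.05, distance = 500))
  b2@textminingP <- c(b2@textminingP, GC = 0.001)
  b2@somaticGenes <- c(b2@somaticGenes, "GB")
  ev2 <- buildEvidenceMatrix(pairs, b2)
  for (cc in c("missense", "eqtl", "textmining", "somatic"))
    expect_true(all(ev2[[cc]] >= ev[[cc]]))
})

test_that("criterion correlations flag degenerate columns honestly", {
  m <- data.frame(missense = c(1L, 0L, 1L, 0L), eqtl = c(1L, 0L, 1L, 0L),
                  textmining = c(0L, 1L, 0L, 1L), ppi_seed = 0L,
                  somatic = c(1L, 1L, 0L, 0L),
                  ko_phenotype = c(0L, 0L, 1L, 1L),
                  functional = c(1L, 0L, 0L, 1L))
  cc <- criterionCorrelation(m)
  expect_equal(cc["missense", "eqtl"], 1)          # duplicated columns
  expect_equal(cc["missense", "textmining"], -1)   # x vs 1 - x
  expect_true(all(is.na(cc["ppi_seed", ])))        # zero variance -> NA
  expect_equal(diag(cc)[c("missense", "somatic")], c(missense = 1,
                                                     somatic = 1))
  expect_true(isSymmetric(unname(cc[criterionCols, criterionCols])))
  expect_error(criterionCorrelation(m[1, , drop = FALSE]), "at least 2")
})

test_that("independent criteria show near-zero correlation at scale", {
  set.seed(2024)
  n <- 10000L
  m <- as.data.frame(setNames(lapply(criterionCols, function(x)
    rbinom(n, 1L, 0.3)), criterionCols))
  cc <- criterionCorrelation(m)
  off <- cc[upper.tri(cc)]
  expect_lt(max(abs(off)), 0.05)
  expect_lt(attr(cc, "maxOffDiagR2"), 0.0025)
})
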