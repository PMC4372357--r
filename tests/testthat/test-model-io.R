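test_that("GWAS table reader parses the published study rows", {
  tab <- fixtureTable1()
  expect_equal(nrow(tab), 64L)
  expect_equal(tab$rsid[1L], "rs10505477")
  expect_equal(tab$odds_ratio[1L], 1.13)
  expect_equal(tab$assoc_p[tab$rsid == "rs6983267"][1L], 8e-28)
  ## one printed CI is inverted (low > high); the reader nulls it
  inverted <- tab$rsid == "rs4779584" & tab$assoc_p == 2e-10
  expect_true(all(is.na(tab$ci_low[inverted])))
})

test_that("GWAS table reader error and degenerate-input contracts hold", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tchrom\tpos\tp\tor", f)
  expect_equal(nrow(readGwasTable(f)), 0L)

  writeLines(c("rsid\tchrom\tp\tor", "rs1\t1\t1e-8\t1.1"), f)
  expect_error(readGwasTable(f), "pos")

  writeLines(c("rsid\tchrom\tpos\tp\tor", "rs1\t1\t100\tnot_a_p\t1.1"), f)
  expect_error(readGwasTable(f), "row 1")
})

test_that("risk-SNP dedup keeps the strongest association per rsid", {
  tab <- fixtureTable1()
  ded <- dedupRiskSnps(tab)
  ## the printed table contains 51 distinct rsids (13 duplicate rows)
  expect_equal(nrow(ded), length(unique(tab$rsid)))
  expect_equal(nrow(ded), 51L)
  expect_equal(ded$assoc_p[ded$rsid == "rs6983267"], 8e-28)
  expect_equal(ded$odds_ratio[ded$rsid == "rs6983267"], 1.2)
  expect_equal(sum(tab$rsid == "rs4939827"), 5L)
  ## first-appearance order is preserved
  expect_equal(ded$rsid, unique(tab$rsid))
})

test_that("dedup is idempotent and never lengthens the table", {
  tab <- fixtureTable1()
  set.seed(42)
  for (i in 1:5) {
    shuf <- tab[sample.int(nrow(tab)), , drop = FALSE]
    d1 <- dedupRiskSnps(shuf)
    expect_lte(nrow(d1), nrow(shuf))
    expect_equal(dedupRiskSnps(d1), d1)
  }
  uniq <- tab[!duplicated(tab$rsid), , drop = FALSE]
  rownames(uniq) <- NULL
  expect_equal(dedupRiskSnps(uniq)$rsid, uniq$rsid)
})

test_that("BED reader honours the 0-based half-open convention", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tgeneA", f)
  gr <- readBed(f)
  expect_equal(length(gr), 1L)
  expect_equal(GenomicRanges::start(gr), 101L)  # BED 100 -> 1-based 101
  expect_equal(GenomicRanges::end(gr), 200L)
  expect_equal(S4Vectors::mcols(gr)$name, "geneA")

  ## unsorted input comes back sorted; overlaps are retained unmerged
  writeLines(c("chr1\t500\t600", "chr1\t100\t300", "chr1\t200\t400"), f)
  gr <- readBed(f)
  expect_equal(GenomicRanges::start(gr), c(101L, 201L, 501L))
  expect_equal(length(gr), 3L)

  writeLines("chr1\t200\t100", f)
  expect_error(readBed(f), "start >= end")
  writeLines("chr1\t1.5\t100", f)
  expect_error(readBed(f), "non-integer")
})

test_that("BED writing round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".bed")
  set.seed(7)
  starts <- sample.int(10000, 50)
  gr <- GenomicRanges::sort(GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), 50, replace = TRUE),
    IRanges::IRanges(starts, starts + sample.int(500, 50))),
    ignore.strand = TRUE)
  S4Vectors::mcols(gr)$name <- sprintf("iv%02d", 1:50)
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(gr))
  expect_equal(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
})

test_that("GMT reader collapses case and enforces the line contracts", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines("craniofacial\tdesc\tBmp4\tBMP4", f)
  sets <- readGeneSets(f)
  expect_equal(sets, list(craniofacial = "BMP4"))

  writeLines(sprintf("cat%02d\tdesc\tG%d", 1:30, 1:30), f)
  expect_length(readGeneSets(f), 30L)

  writeLines("noMembers\tdesc", f)
  expect_error(readGeneSets(f), "fewer than 3")
  writeLines(c("a\td\tG1", "a\td\tG2"), f)
  expect_error(readGeneSets(f), "duplicate set name")
})

test_that("edge list reader canonicalizes undirected edges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "A\tB", "B\tA", "A\tA"), f)
  el <- readEdgeList(f)
  expect_equal(nrow(el), 1L)
  expect_equal(el$from, "A")
  expect_equal(el$to, "B")
  expect_equal(attr(el, "nodes"), 2L)

  writeLines("from\tto", f)
  empty <- readEdgeList(f)
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "nodes"), 0L)
})

test_that("drug table reader exposes distinct target counts by status", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTable <- function(df) write.table(df, f, sep = "\t", quote = FALSE,
                                         row.names = FALSE)
  writeTable(data.frame(
    drug = c("d1", "d2", "d3"), target = c("T1", "T1", "T2"),
    status = c("approved", "clinical", "approved"),
    indication = c("crc", "other", "crc"),
    crc_approved = c(1, 0, 1)))
  dt <- readDrugTable(f)
  cnt <- attr(dt, "target_counts")
  expect_equal(unname(cnt["total"]), 2L)        # same gene, two drugs
  expect_equal(unname(cnt["crc_approved"]), 2L)
  expect_equal(sum(dt$target == "T1"), 2L)

  writeTable(data.frame(drug = "d", target = "T", status = "banana",
                        indication = "x", crc_approved = 0))
  expect_error(readDrugTable(f), "unknown status")
})

test_that("a resource bundle round-trips through its directory form", {
  b <- tinyBundle()
  d <- withr::local_tempdir()
  writeBundle(b, d)
  b2 <- readBundle(d)
  expect_equal(b2@riskSnps, b@riskSnps)
  expect_equal(b2@ld, b@ld)
  expect_equal(S4Vectors::mcols(b2@genes)$symbol,
               S4Vectors::mcols(b@genes)$symbol)
  expect_equal(GenomicRanges::ranges(b2@genes),
               GenomicRanges::ranges(b@genes))
  expect_equal(b2@eqtl, b@eqtl)
  expect_equal(b2@textminingP, b@textminingP)
  expect_equal(sort(b2@somaticGenes), sort(b@somaticGenes))
  expect_equal(b2@koCategories, b@koCategories)
  expect_equal(b2@network, b@network, ignore_attr = TRUE)
  expect_equal(b2@drugs$crc_approved, b@drugs$crc_approved)
  expect_equal(b2@geneUniverseN, b@geneUniverseN)
  expect_equal(names(b2@peaks), names(b@peaks))
  expect_equal(GenomicRanges::ranges(b2@peaks[[1L]]),
               GenomicRanges::ranges(b@peaks[[1L]]))
})

test_that("pipeline config round-trips through YAML and validates", {
  cfg <- pipelineConfig(r2Threshold = 0.9, permutationIters = 500L,
                        rngSeed = 99L, easeAdjust = TRUE)
  f <- withr::local_tempfile(fileext = ".yaml")
  writePipelineConfig(cfg, f)
  cfg2 <- readPipelineConfig(f)
  expect_equal(cfg2@r2Threshold, 0.9)
  expect_equal(cfg2@permutationIters, 500L)
  expect_true(cfg2@easeAdjust)
  expect_error(pipelineConfig(r2Threshold = 1.5), "r2Threshold")
  expect_error(pipelineConfig(permutationIters = 0L), "permutationIters")
})
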