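## Packaged fixtures transcribed from the published summary tables, plus
## the drug-overlap scenario constructed in code.

fixturePath <- function(name)
  system.file("extdata", name, package = "snp2drug", mustWork = TRUE)

#' Published risk-SNP table fixture
#'
#' The 64 printed GWAS-catalogue rows (one per study record; rsids recur
#' across studies). Chromosomes are taken from the cytoband label;
#' basepair positions are not printed and are `NA`. One row carries an
#' inverted confidence interval in print, which the reader nulls out.
#'
#' @return data.frame in the [readGwasTable()] layout (64 rows).
#' @seealso [dedupRiskSnps()]
#' @export
fixtureTable1 <- function() {
  readGwasTable(fixturePath("table1_risk_snps.tsv"))
}

#' Published evidence-matrix fixture
#'
#' The 35 biological-risk-gene rows (score >= 2) with their seven
#' criterion indicators, nearest-gene flag and printed score. One row
#' (SYNJ2) prints one fewer indicator cell than the header implies; it
#' is transcribed with the missing cell as 0 — any placement of the
#' missing cell is consistent with its printed score of 2 — and flagged
#' in the `ambiguous` column.
#'
#' @return data.frame: snp, gene, nearest, the seven indicator columns,
#'   `score` (as printed) and `ambiguous`.
#' @export
fixtureTable2 <- function() {
  df <- readTsv(fixturePath("table2_evidence.tsv"), "evidence fixture")
  df$nearest <- as.logical(df$nearest)
  df
}

#' Drug-overlap scenario fixture
#'
#' Synthetic gene labels realizing the published overlap cardinalities
#' exactly: a universe of N = 11303 genes, an expanded risk set x of 584
#' (31 biological genes plus 553 one-hop interactors), y = 8 approved
#' disease-drug targets of which 5 fall in x, and z = 871 all-drug
#' targets (y a subset of z) of which 70 fall in x.
#'
#' @return List: `universeN`, `x`, `y`, `z` (character label sets).
#' @examples
#' sc <- fixtureOverlapScenario()
#' overlapTest(sc$universeN, sc$y, sc$x)  # 12.09-fold, p = 1.78e-5
#' @export
fixtureOverlapScenario <- function() {
  y <- sprintf("CRCTGT%02d", 1:8)
  zOnly <- sprintf("TGT%04d", 1:863)          # z \ y
  xOnly <- sprintf("RISK%04d", 1:514)         # x outside z
  x <- c(y[1:5], zOnly[1:65], xOnly)          # 5 + 65 + 514 = 584
  list(universeN = 11303L, x = x, y = y, z = c(y, zOnly))
}
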