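## Network pharmacology: one-hop PPI expansion of the biological risk
## genes and the drug-target overlap report.

#' One-hop neighbourhood expansion
#'
#' Seeds union all of their direct interaction partners — exactly one
#' hop. Seeds absent from the network contribute no neighbours but stay
#' in the returned set. Output is independent of edge order and
#' orientation.
#'
#' @param seeds Character set of seed gene symbols.
#' @param network Edge data.frame (from, to), any orientation.
#' @return Character vector, sorted: seeds plus direct neighbours.
#' @examples
#' oneHopExpand("A", data.frame(from = c("A", "B"), to = c("B", "C")))
#' @export
oneHopExpand <- function(seeds, network) {
  seeds <- unique(normSymbol(seeds))
  a <- normSymbol(network$from); b <- normSymbol(network$to)
  nb <- c(b[a %in% seeds], a[b %in% seeds])
  sort(unique(c(seeds, nb)))
}

#' Drug-target overlap report
#'
#' The repositioning statistic: expand the biological risk genes one hop
#' through the PPI network into the set x, then test x for enrichment of
#' (i) the targets of approved disease drugs (set y: rows flagged
#' `crc_approved`) and (ii) the targets of all drugs (set z), each with
#' the exact hypergeometric upper tail at universe size `universeN`.
#' Also reports the relative fold (k_y/K_y)/(k_z/K_z), a one-sided
#' Fisher comparison of the two target sets' hit rates, and the flat
#' connection table risk SNP -> risk gene -> interacting gene -> drug
#' for every drug whose target lands in x (paths de-duplicated on
#' (risk gene, interacting gene, drug) and ordered lexicographically).
#'
#' @param scoreRecords Scored evidence rows ([scoreRows()]); rows with
#'   `biological == TRUE` seed the expansion.
#' @param network Edge data.frame (from, to).
#' @param drugs Drug-target data.frame ([readDrugTable()] layout).
#' @param universeN Hypergeometric universe size N.
#' @param cfg A [PipelineConfig-class] (EASE switch only).
#' @return A [DrugOverlapReport-class]. With no biological rows the
#'   tests are degenerate (n = 0, p = 1) and attribute `empty` is set.
#' @export
drugOverlapReport <- function(scoreRecords, network, drugs, universeN,
                              cfg = pipelineConfig()) {
  seeds <- distinctGenes(scoreRecords[scoreRecords$biological, ,
                                      drop = FALSE])
  x <- if (length(seeds)) oneHopExpand(seeds, network) else character()
  y <- unique(normSymbol(drugs$target[drugs$crc_approved]))
  z <- unique(normSymbol(drugs$target))
  crc <- overlapTest(universeN, y, x, ease = cfg@easeAdjust)
  allT <- overlapTest(universeN, z, x, ease = cfg@easeAdjust)
  rel <- relativeFold(crc, allT)
  cmp <- if (allT@overlapK > 0L && crc@categoryK > 0L)
    compareTargetSets(crc, allT) else NA_real_
  conn <- .connectionPaths(scoreRecords, seeds, network, drugs, x)
  rep <- new("DrugOverlapReport", xSet = x, seedGenes = seeds,
             crcTest = crc, allTest = allT,
             relativeFold = as.numeric(rel), comparisonP = cmp,
             connections = conn)
  if (!length(seeds)) attr(rep, "empty") <- TRUE
  rep
}

.connectionPaths <- function(scoreRecords, seeds, network, drugs, x) {
  empty <- data.frame(snp = character(), risk_gene = character(),
                      ppi_gene = character(), drug = character(),
                      indication = character(), stringsAsFactors = FALSE)
  hitRows <- drugs[normSymbol(drugs$target) %in% x, , drop = FALSE]
  if (!nrow(hitRows) || !length(seeds)) return(empty)
  a <- normSymbol(network$from); b <- normSymbol(network$to)
  snpOf <- split(scoreRecords$snp[scoreRecords$biological],
                 normSymbol(scoreRecords$gene[scoreRecords$biological]))
  rows <- list()
  for (i in seq_len(nrow(hitRows))) {
    tgt <- normSymbol(hitRows$target[i])
    ## risk genes reaching this target: the target itself if a seed,
    ## plus seeds adjacent to it
    riskGenes <- unique(c(if (tgt %in% seeds) tgt,
                          intersect(c(a[b == tgt], b[a == tgt]), seeds)))
    for (rg in riskGenes)
      rows[[length(rows) + 1L]] <- data.frame(
        snp = snpOf[[rg]], risk_gene = rg, ppi_gene = tgt,
        drug = hitRows$drug[i], indication = hitRows$indication[i],
        stringsAsFactors = FALSE)
  }
  out <- unique(do.call(rbind, c(list(empty), rows)))
  out <- out[order(out$risk_gene, out$ppi_gene, out$drug, out$snp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the connection graph as DOT
#'
#' Bipartite-ish rendering of the connection table (risk gene ->
#' interacting gene -> drug) for graph tooling.
#'
#' @param report A [DrugOverlapReport-class].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
writeConnectionsDot <- function(report, path) {
  cn <- report@connections
  q <- function(x) sprintf('"%s"', gsub('"', "'", x))
  lines <- c("graph connections {",
             unique(sprintf("  %s -- %s;", q(cn$risk_gene), q(cn$ppi_gene))),
             unique(sprintf("  %s -- %s;", q(cn$ppi_gene), q(cn$drug))),
             "}")
  writeLines(lines, path)
  invisible(path)
}
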